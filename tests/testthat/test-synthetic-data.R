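test_that("clone fields evaluate to bounded, saturating fractions", {
  f1 <- make_clone_field(c(100, 100, 100),
                         list(list(center = c(50, 50, 50),
                                   scale = c(10, 10, 10), peak = 0.8)), 0)
  expect_equal(eval_field(f1, cbind(50, 50, 50)), 0.8)
  f0 <- make_clone_field(c(10, 10, 10), background_fraction = 0.05)
  set.seed(1)
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  expect_equal(eval_field(f0, pts), rep(0.05, 10))
  # two identical clones saturate, they do not add
  f2 <- make_clone_field(c(100, 100, 100), list(
    list(center = c(50, 50, 50), scale = c(10, 10, 10), peak = 0.6),
    list(center = c(50, 50, 50), scale = c(10, 10, 10), peak = 0.6)), 0)
  expect_equal(eval_field(f2, cbind(50, 50, 50)), 0.6)
  # bounded in [0, 1] everywhere, and a pure function of position
  fb <- make_clone_field(c(100, 100, 100), list(
    list(center = c(40, 40, 40), scale = c(30, 30, 30), peak = 1),
    list(center = c(60, 60, 60), scale = c(30, 30, 30), peak = 0.9)), 0.2)
  pts <- matrix(runif(300, 0, 100), ncol = 3)
  v1 <- eval_field(fb, pts)
  expect_true(all(v1 >= 0 & v1 <= 1))
  expect_identical(v1, eval_field(fb, pts))
})

test_that("clone validation names the offending clone", {
  expect_error(
    make_clone_field(c(10, 10, 10),
                     list(list(center = c(5, 5, 5), scale = c(1, 1, 1),
                               peak = 0.5),
                          list(center = c(50, 5, 5), scale = c(1, 1, 1),
                               peak = 0.5))),
    "clone 2")
  expect_error(
    make_clone_field(c(10, 10, 10),
                     list(list(center = c(5, 5, 5), scale = c(1, 1, 1),
                               peak = 1.2))),
    "peak")
})

test_that("position census matches the grid design", {
  # 8 adjacent 8x6 blocks on one section: the 384 candidate positions
  expect_equal(nrow(enumerate_positions(grid_layout(n_blocks = 8,
                                                    z_planes = 0))), 384)
  one <- grid_layout(n_blocks = 1, rows = 1, cols = 1, z_planes = 0)
  p1 <- enumerate_positions(one)
  expect_equal(nrow(p1), 1)
  expect_equal(c(p1$x_um, p1$y_um), c(0, 0))
  expect_equal(nrow(enumerate_positions(default_layout())), 480)
  # total candidates = blocks * rows * cols * planes, for assorted shapes
  for (cfg in list(c(2, 3, 4, 2), c(1, 6, 8, 5), c(3, 2, 2, 1))) {
    lay <- grid_layout(n_blocks = cfg[1], rows = cfg[2], cols = cfg[3],
                       z_planes = seq_len(cfg[4]) * 50)
    expect_equal(nrow(enumerate_positions(lay)), prod(cfg))
  }
})

test_that("layout validation: overlap, pitch and z ordering", {
  expect_error(grid_layout(pitch_xy = 100, z_planes = 0), "overlap")
  expect_error(grid_layout(z_planes = c(0, 100, 100)), "increasing")
  expect_error(grid_layout(n_blocks = 2, z_planes = 0,
                           block_offsets = rbind(c(0, 0), c(100, 0))),
               "overlap")
  # disc radius from the 25,000 um^2 disc
  expect_equal(disc_radius(grid_layout(z_planes = 0)), sqrt(25000 / pi))
})

test_that("well identifiers round-trip through the position table", {
  lay <- grid_layout(n_blocks = 2, z_planes = c(0, 50))
  pos <- enumerate_positions(lay)
  expect_false(anyDuplicated(pos$well) > 0)
  expect_false(anyDuplicated(pos[, c("block", "row", "col", "z_index")]) > 0)
  expect_false(anyDuplicated(pos[, c("x_um", "y_um", "z_um")]) > 0)
})

test_that("simulated traces satisfy the area identity and are reproducible", {
  p0 <- quiet_params()
  # zero fraction: no mutant or heteroduplex signal at all
  a0 <- simulate_trace(0, p0, seed = 1)$meta$true_areas
  expect_equal(unname(a0[c("mut", "hd1", "hd2")]), c(0, 0, 0))
  # closed-form round trip through the quantification identity
  for (p in c(0.01, 0.2, 0.5, 0.77)) {
    a <- simulate_trace(p, p0, seed = 1)$meta$true_areas
    expect_equal((a[["mut"]] + 0.5 * (a[["hd1"]] + a[["hd2"]])) /
                   sum(a[c("wt", "mut", "hd1", "hd2")]), p,
                 tolerance = 1e-12)
  }
  # same seed, same params: bit-identical traces
  t1 <- simulate_trace(0.2, trace_params(), seed = 99)
  t2 <- simulate_trace(0.2, trace_params(), seed = 99)
  expect_identical(t1$sample_channel, t2$sample_channel)
  expect_identical(t1$standard_channel, t2$standard_channel)
  t3 <- simulate_trace(0.2, trace_params(), seed = 100)
  expect_false(identical(t1$sample_channel, t3$sample_channel))
})

test_that("unresolvable peak layouts are rejected", {
  expect_error(trace_params(apex = c(std1 = 150, std2 = 210, wt = 400,
                                     mut = 410, hd1 = 510, hd2 = 560,
                                     ss = 650)),
               "unresolvable")
  expect_error(trace_params(width = c(std1 = 6, std2 = 6, wt = 0, mut = 6,
                                      hd1 = 6, hd2 = 6, ss = 6)),
               "width")
})

test_that("dropout is Bernoulli with explicit carriage of missing wells", {
  pos <- enumerate_positions(grid_layout(n_blocks = 2, z_planes = 0))
  expect_equal(sum(apply_dropout(pos, 0, seed = 1)), 0)
  expect_equal(sum(apply_dropout(pos, 1, seed = 1)), nrow(pos))
  big <- data.frame(i = seq_len(10000))
  m <- sum(apply_dropout(big, 0.25, seed = 42))
  expect_lt(abs(m - 2500), 3 * sqrt(10000 * 0.25 * 0.75))
  # reproducible under the same seed
  expect_identical(apply_dropout(pos, 0.3, seed = 7),
                   apply_dropout(pos, 0.3, seed = 7))
})

test_that("simulate_dataset writes traces and a faithful manifest", {
  dir <- withr::local_tempdir()
  f <- make_clone_field(c(2000, 1500, 100),
                        list(list(center = c(1000, 700, 50),
                                  scale = c(500, 400, 80), peak = 0.7)),
                        0.02)
  lay <- grid_layout(n_blocks = 1, rows = 3, cols = 4, z_planes = c(0, 100))
  sim <- simulate_dataset(f, lay, quiet_params(), dropout_prob = 0.3,
                          seed = 5, dir = dir)
  expect_equal(nrow(sim$manifest), 24)
  expect_setequal(list.files(dir),
                  c("manifest.csv",
                    paste0(sim$manifest$well[!sim$manifest$missing], ".csv")))
  # true fractions come from the field at the disc centers
  xyz <- as.matrix(sim$manifest[, c("x_um", "y_um", "z_um")])
  expect_equal(sim$manifest$true_fraction, eval_field(f, xyz))
  # per-well child seeding: regenerating one well in isolation matches
  i <- which(!sim$manifest$missing)[1]
  solo <- simulate_trace(sim$manifest$true_fraction[i], quiet_params(),
                         seed = derive_seed(5, "trace", i))
  expect_identical(solo$sample_channel, sim$traces[[i]]$sample_channel)
})
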