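test_that("packaged 55-artery tree loads with the tabulated geometry", {
  tree <- default_tree()
  expect_s3_class(tree, "arterial_tree")
  expect_equal(nrow(tree), 55)
  expect_equal(sum(tree$terminal), 28)

  asc <- tree[tree$id == 1, ]
  expect_equal(asc$length_cm, 4)
  expect_equal(asc$r_in_cm, 1.525)
  expect_equal(asc$r_out_cm, 1.42)
  expect_true(is.na(asc$parent_id))

  rad <- tree[tree$id == 8, ]
  expect_true(rad$terminal)
  expect_equal(rad$RT, 4.41e4)        # stored in plain CGS after the 1e4 scale
  expect_equal(rad$CT, 1.09e-6)
})

test_that("tree CSV round-trips through write_tree_csv/read_tree_csv", {
  tree <- default_tree()
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree_csv(tree, path)
  back <- read_tree_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tree), tolerance = 1e-12)
})

test_that("tree validation rejects malformed tables", {
  tree <- default_tree()

  three_kids <- tree
  # reroute a segment so one parent gets 3 children
  three_kids$parent_id[three_kids$id == 14] <- 13L
  expect_error(arterial_tree(three_kids), class = "pw_tree_error")

  neg <- tree
  neg$length_cm[5] <- -1
  expect_error(arterial_tree(neg), class = "pw_tree_error")

  orphan <- tree
  orphan$parent_id[orphan$id == 20] <- 99L
  expect_error(arterial_tree(orphan), class = "pw_tree_error")

  two_roots <- tree
  two_roots$parent_id[two_roots$id == 2] <- NA_integer_
  expect_error(arterial_tree(two_roots), class = "pw_tree_error")

  half_term <- tree
  half_term$CT[half_term$id == 8] <- NA_real_
  expect_error(arterial_tree(half_term), class = "pw_tree_error")
})

test_that("subject scaling multiplies geometry by S and terminals by S^-3 / S^3", {
  tree <- default_tree()

  ident <- scale_tree(tree, 175, s_r = 1, s_c = 1)
  expect_equal(ident$length_cm, tree$length_cm)
  expect_equal(ident$RT, tree$RT)

  tall <- scale_tree(tree, 183.75)   # S = 1.05
  expect_equal(tall$length_cm[tall$id == 1], 4.2)
  term <- tree$terminal
  expect_equal(tall$RT[term] / tree$RT[term], rep(1 / 1.157625, sum(term)))
  expect_equal(tall$CT[term] / tree$CT[term], rep(1.157625, sum(term)))

  res_only <- scale_tree(tree, 175, s_r = 1.56)
  expect_equal(res_only$RT[term], tree$RT[term] * 1.56)
  expect_equal(res_only$r_in_cm, tree$r_in_cm)

  expect_error(scale_tree(tree, -170), class = "pw_tree_error")
})

test_that("scaled tree volume scales with S^3", {
  tree <- default_tree()
  s <- 1.07
  scaled <- scale_tree(tree, 175 * s)
  expect_equal(sum(segment_volume(scaled)), s^3 * sum(segment_volume(tree)),
               tolerance = 1e-10)
})

test_that("segment radius tapers exponentially (log-linear in x)", {
  tree <- default_tree()
  expect_equal(segment_radius(tree, 1, 0), 1.525)
  expect_equal(segment_radius(tree, 1, 4), 1.42)
  # untapered radial artery is constant
  expect_equal(segment_radius(tree, 8, c(0, 7, 22)), rep(0.175, 3))
  # log r interpolates linearly between the end values
  x <- seq(0, 4, length.out = 11)
  lr <- log(segment_radius(tree, 1, x))
  expect_equal(lr, seq(log(1.525), log(1.42), length.out = 11), tolerance = 1e-12)
  expect_error(segment_radius(tree, 1, 5), class = "pw_tree_error")
})

test_that("wall modulus follows the exponential-plus-offset law and is monotone", {
  w <- wall_model()        # k1 = 2, k2 = -22.53, k3 = 8.65 nominal
  direct <- function(r) (4 / 3) * (2e7 * exp(-22.53 * r) + 8.65e5)
  expect_equal(wall_modulus(1.525, w), direct(1.525), tolerance = 1e-12)
  expect_equal(wall_modulus(1.525, w), 1.1533e6, tolerance = 3e-4)
  expect_equal(wall_modulus(0.175, w), direct(0.175), tolerance = 1e-12)
  expect_equal(wall_modulus(0.175, w), 1.6707e6, tolerance = 3e-4)

  w0 <- wall_model(k1 = 0)
  expect_equal(wall_modulus(c(0.1, 0.5, 2), w0), rep(4 / 3 * 8.65e5, 3))

  # non-increasing everywhere; strictly decreasing until the exponential term
  # falls below double-precision resolution of the k3 offset
  r <- seq(0.05, 2, length.out = 200)
  expect_true(all(diff(wall_modulus(r, w)) <= 0))
  r_small <- seq(0.05, 1, length.out = 100)
  expect_true(all(diff(wall_modulus(r_small, w)) < 0))
  expect_error(wall_model(k2 = 1), class = "pw_wall_error")
})

test_that("along-tree path lengths accumulate segment lengths", {
  tree <- default_tree()
  # aortic arch inlet (id 2) to femoral midpoint (id 38):
  # 3+4+6+11+5+2+2+13+8+6+15 + 22 = 97 cm
  expect_equal(tree_path_length(tree, 2, 38, from_frac = 0, to_frac = 0.5), 97)
  # aorta inlet to radial midpoint: 4+4+4+40 + 11 = 63
  expect_equal(tree_path_length(tree, 1, 8, from_frac = 0, to_frac = 0.5), 63)
})
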