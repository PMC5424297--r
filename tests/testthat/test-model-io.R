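test_that("parsing the worked two-reaction example reproduces its stoichiometry", {
  dir <- system.file("extdata", "two_reaction_example", package = "massaction")
  m <- parse_model(dir)
  expect_s3_class(m, "reaction_model")
  expect_equal(m$n_reactions, 2)
  expect_equal(m$n_species, 3)
  expect_equal(m$reactant_matrix, rbind(c(1, 1, 0), c(0, 0, 1)),
               ignore_attr = TRUE)
  expect_equal(m$product_matrix, rbind(c(0, 0, 1), c(1, 1, 0)),
               ignore_attr = TRUE)
  expect_equal(m$kinetic_constants, c(2, 3))
  expect_equal(m$initial_state, c(1, 0.5, 2))
  expect_equal(m$sampling_times, c(0, 50))
  # the species-1 ODE encoded by this model is -k1*X1*X2 + k2*X3
  f <- evaluate_derivatives(build_encoding(m), m$initial_state)
  expect_equal(f[1], -2 * 1 * 0.5 + 3 * 2)
})

test_that("parse errors name the problem: missing files, empty or ragged input", {
  base <- system.file("extdata", "two_reaction_example", package = "massaction")
  expect_error(parse_model(tempfile("nodir")), "not found")

  d <- withr::local_tempdir()
  file.copy(list.files(base, full.names = TRUE), d)
  writeLines("# nothing here", file.path(d, "left_side"))
  expect_error(parse_model(d), "no reactions")

  file.copy(list.files(base, full.names = TRUE), d, overwrite = TRUE)
  writeLines("2", file.path(d, "c_vector"))  # M - 1 entries
  expect_error(parse_model(d), "dimension mismatch")

  file.copy(list.files(base, full.names = TRUE), d, overwrite = TRUE)
  writeLines(c("1 1 0", "0 x 1"), file.path(d, "left_side"))
  expect_error(parse_model(d), "non-numeric")

  file.copy(list.files(base, full.names = TRUE), d, overwrite = TRUE)
  file.remove(file.path(d, "t_vector"))
  expect_error(parse_model(d), "missing model file")
})

test_that("comments, blank lines and the optional files are honoured", {
  d <- withr::local_tempdir()
  writeLines(c("# A", "", "1 0", "0 1"), file.path(d, "left_side"))
  writeLines(c("0 1", "1 0"), file.path(d, "right_side"))
  writeLines(c("# rates", "1", "2"), file.path(d, "c_vector"))
  writeLines("0.3 0.7", file.path(d, "M_0"))
  writeLines(c("0", "1", "2"), file.path(d, "t_vector"))
  writeLines("1", file.path(d, "cs_vector"))       # record only species 2 (0-based)
  writeLines(c("glu", "pyr"), file.path(d, "species_names"))
  m <- parse_model(d)
  expect_equal(m$species_names, c("glu", "pyr"))
  expect_equal(m$recorded_species, 1L)
  r <- simulate_model(m)
  expect_equal(colnames(r$states), "pyr")
})

test_that("validation reports violations as data, one record per offence", {
  m <- two_reaction_model()
  expect_equal(nrow(validate_model(m)), 0)

  # trimolecular reactant side: order 3 is rejected
  bad <- new_reaction_model(rbind(c(2, 1, 0)), rbind(c(0, 0, 1)), 1,
                            c(1, 1, 1), c(0, 1))
  v <- validate_model(bad)
  expect_equal(v$rule, "reaction order > 2")
  expect_equal(v$index, 1L)

  # dimerization 2A is an allowed second-order case
  dimer <- new_reaction_model(rbind(c(2, 0)), rbind(c(0, 1)), 1, c(1, 0), c(0, 1))
  expect_equal(nrow(validate_model(dimer)), 0)

  # zero-order source refused by default, admitted by the permissive flag
  src <- new_reaction_model(rbind(c(0, 0)), rbind(c(1, 0)), 1, c(0, 0), c(0, 1))
  expect_equal(validate_model(src)$rule, "reaction order < 1")
  expect_equal(nrow(validate_model(src, allow_zero_order = TRUE)), 0)

  # non-positive kinetic constant
  k0 <- new_reaction_model(rbind(c(1, 0)), rbind(c(0, 1)), 0, c(1, 0), c(0, 1))
  expect_match(validate_model(k0)$rule, "non-positive kinetic constant")

  # several violations reported together
  multi <- new_reaction_model(rbind(c(1, 0), c(1, 2)), rbind(c(0, 1), c(2, 1)),
                              c(-1, 1), c(1, -2), c(1, 0.5))
  v <- validate_model(multi)
  expect_setequal(v$rule, c("reaction order > 2", "non-positive kinetic constant",
                            "negative initial concentration", "sampling times"))
})

test_that("a written model parses back identical, over seeded random models", {
  for (seed in 1:20) {
    m <- generate_random_model(16, 12, seed = seed)
    d <- tempfile("model")
    write_model(m, d)
    m2 <- parse_model(d)
    expect_equal(m2$reactant_matrix, m$reactant_matrix, ignore_attr = TRUE)
    expect_equal(m2$product_matrix, m$product_matrix, ignore_attr = TRUE)
    expect_identical(m2$kinetic_constants, m$kinetic_constants)
    expect_identical(m2$initial_state, m$initial_state)
    expect_identical(m2$sampling_times, m$sampling_times)
    unlink(d, recursive = TRUE)
  }
})

test_that("time series survive a write/read round trip bit-for-bit", {
  r <- simulate_model(ab_model(times = seq(0, 5, length.out = 10)))
  path <- withr::local_tempfile()
  write_timeseries(r, path)
  lines <- readLines(path)
  expect_equal(length(lines), 11)  # header + one row per instant
  expect_equal(strsplit(lines[1], "\t")[[1]], c("time", "X1", "X2"))
  back <- read_timeseries(path)
  expect_identical(back$times, r$times)
  expect_identical(unname(back$states), unname(r$states))
})
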