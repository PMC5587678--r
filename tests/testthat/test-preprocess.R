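# Medium application, reversible splitting, FVA reduction.

test_that("apply_medium rewrites exchange bounds and validates ids", {
  m <- make_fixture("linear_chain")
  empty <- tibble::tibble(reaction = character(0), lower_bound = numeric(0),
                          upper_bound = numeric(0))
  expect_equal(apply_medium(m, empty)$lb, m$lb)   # identity

  closed <- apply_medium(m, tibble::tibble(reaction = "EX_A",
                                           lower_bound = 0,
                                           upper_bound = 1000))
  expect_equal(max_flux(closed), 0)   # sole substrate shut off

  expect_error(apply_medium(m, tibble::tibble(reaction = "r1",
                                              lower_bound = 0,
                                              upper_bound = 1)),
               "non-exchange")
  expect_error(apply_medium(m, tibble::tibble(reaction = "EX_A",
                                              lower_bound = 1,
                                              upper_bound = 0)),
               "lb > ub")
})

test_that("closed-by-default shuts unlisted exchanges only", {
  iso <- make_fixture("isozyme_demo")   # exchanges EX_A (uptake), EX_F
  med <- tibble::tibble(reaction = "EX_F", lower_bound = 0,
                        upper_bound = 1000)
  out <- apply_medium(iso, med, closed_by_default = TRUE)
  expect_equal(out$lb[match("EX_A", out$rxns)], 0)
  expect_equal(max_flux(out), 0)
})

test_that("split_reversible produces a valid irreversible expansion", {
  m <- make_fixture("linear_chain")   # one reversible exchange
  s <- split_reversible(m)
  expect_s3_class(s, "irreversible_model")
  expect_length(s$rxns, 5)
  expect_true(all(s$lb == 0))
  j <- match("EX_A_rev", s$rxns)
  expect_equal(as.numeric(s$S[, j]), -as.numeric(s$S[, match("EX_A", s$rxns)]))
  expect_equal(s$gpr[j], m$gpr[match("EX_A", m$rxns)])
  expect_equal(s$ub[j], 10)   # -lb of the parent

  # irreversible model passes through unchanged in column count
  fig <- make_fixture("figure1_like")
  expect_length(split_reversible(fig)$rxns, length(fig$rxns))
})

test_that("splitting preserves the maximal target flux", {
  for (nm in c("linear_chain", "isozyme_demo", "complex_demo")) {
    m <- make_fixture(nm)
    expect_equal(max_flux(split_reversible(m)), max_flux(m),
                 tolerance = 1e-9)
  }
})

test_that("fva_reduce removes exactly the dead columns", {
  m <- chain_with_dead_end()
  red <- fva_reduce(split_reversible(m))
  expect_false("dead" %in% red$rxns)
  expect_false("X" %in% red$mets)
  expect_setequal(setdiff(split_reversible(m)$rxns, red$rxns), "dead")
  expect_equal(max_flux(red), max_flux(m), tolerance = 1e-9)
})

test_that("fva_reduce is idempotent and errors on a blocked target", {
  red <- fva_reduce(split_reversible(make_fixture("isozyme_demo")))
  red2 <- fva_reduce(red)
  expect_equal(red2$rxns, red$rxns)

  m <- make_fixture("linear_chain")
  closed <- apply_medium(m, tibble::tibble(reaction = "EX_A",
                                           lower_bound = 0,
                                           upper_bound = 0))
  expect_error(fva_reduce(split_reversible(closed)),
               "target task infeasible")
})

test_that("infinite bounds are capped at the configured finite value", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("in", "out")))
  m <- metabolic_model("A", c("in", "out"), S, lb = c(0, 0),
                       ub = c(Inf, Inf), target = "out")
  s <- split_reversible(m, inf_bound = 1e3)
  expect_equal(s$ub, c(1000, 1000))
})
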