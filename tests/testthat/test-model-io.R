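# Model containers, JSON/SBML round trips, expression tables, result files.

test_that("the smallest valid model loads from JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini",
    "metabolites": [{"id": "A"}],
    "reactions": [
      {"id": "r_in", "metabolites": {"A": 1}, "lower_bound": 0,
       "upper_bound": 10, "gene_reaction_rule": ""},
      {"id": "r_out", "metabolites": {"A": -1}, "lower_bound": 0,
       "upper_bound": 10, "gene_reaction_rule": "g1",
       "objective_coefficient": 1}
    ],
    "genes": [{"id": "g1"}]
  }', path)
  m <- read_json_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_length(m$mets, 1)
  expect_length(m$rxns, 2)
  expect_equal(m$target, "r_out")
})

test_that("JSON write -> read is the identity on fixtures", {
  for (nm in c("linear_chain", "isozyme_demo", "complex_demo",
               "figure1_like")) {
    m <- make_fixture(nm)
    path <- withr::local_tempfile(fileext = ".json")
    write_json_model(m, path)
    m2 <- read_json_model(path)
    expect_equal(m2$mets, m$mets)
    expect_equal(m2$rxns, m$rxns)
    expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
    expect_equal(m2$lb, m$lb)
    expect_equal(m2$ub, m$ub)
    expect_equal(m2$gpr, m$gpr)
    expect_equal(sort(m2$genes), sort(m$genes))
    expect_equal(m2$target, m$target)
  }
})

test_that("SBML and JSON readers agree on equivalent content", {
  m <- make_fixture("isozyme_demo")
  sbml <- withr::local_tempfile(fileext = ".xml")
  json <- withr::local_tempfile(fileext = ".json")
  write_sbml_model(m, sbml)
  write_json_model(m, json)
  ms <- read_sbml_model(sbml)
  mj <- read_json_model(json)
  expect_equal(ms$mets, mj$mets)
  expect_equal(ms$rxns, mj$rxns)
  expect_equal(as.matrix(ms$S), as.matrix(mj$S), ignore_attr = TRUE)
  expect_equal(ms$lb, mj$lb)
  expect_equal(ms$ub, mj$ub)
  # rules may differ in parenthesisation but must be logically identical
  expect_equal(lapply(ms$gpr, parse_gpr), lapply(mj$gpr, parse_gpr))
  expect_equal(ms$target, mj$target)
})

test_that("SBML without GPRs yields empty rules; corrupt files error", {
  m <- make_fixture("linear_chain")
  m$gpr <- rep("", 4); m$rules <- lapply(m$gpr, parse_gpr)
  m$genes <- character(0)
  sbml <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(m, sbml)
  ms <- read_sbml_model(sbml)
  expect_true(all(ms$gpr == ""))

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_sbml_model(bad), "cannot parse|no <model>")
  expect_error(read_sbml_model(withr::local_tempfile()), "no such file")
})

test_that("model validation catches broken inputs", {
  path <- withr::local_tempfile(fileext = ".json")
  # GPR references a gene missing from the declared gene list
  writeLines('{
    "metabolites": [{"id": "A"}],
    "reactions": [
      {"id": "r1", "metabolites": {"A": 1}, "lower_bound": 0,
       "upper_bound": 10, "gene_reaction_rule": "gX",
       "objective_coefficient": 1}
    ],
    "genes": [{"id": "g1"}]
  }', path)
  expect_error(read_json_model(path), "gX")

  expect_error(metabolic_model("A", "r1", matrix(1, 1, 1), lb = 2, ub = 1,
                               target = "r1"), "lower bound")
  expect_error(metabolic_model("A", "r1", matrix(1, 1, 1), lb = 0, ub = 1,
                               target = "nope"), "target")
})

test_that("expression tables honour the inclusive call threshold", {
  path <- write_tsv_lines(c("gene\ts1", "g1\t5.0", "g4\t-1.0"))
  prof <- read_expression_table(path, threshold = 5)
  calls <- expression_calls(prof)
  expect_true(calls$s1[calls$gene == "g1"])    # z = 5 exactly: expressed
  expect_false(calls$s1[calls$gene == "g4"])
  expect_equal(classify_genes(prof), "g4")
})

test_that("expression reader rejects duplicates, bad cells, no samples", {
  expect_error(read_expression_table(
    write_tsv_lines(c("gene\ts1", "g1\t1", "g1\t2"))), "duplicate")
  expect_error(read_expression_table(
    write_tsv_lines(c("gene\ts1", "g1\tNaX"))), "non-numeric")
  expect_error(read_expression_table(
    write_tsv_lines(c("gene", "g1"))), "no sample columns")
})

test_that("gMCS results survive a JSON-lines round trip", {
  res <- enumerate_gmcs(make_fixture("complex_demo"), genes_L = "gB",
                        target_gene = "gA")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_results(res, path)
  back <- read_results(path)
  expect_equal(back$target_gene, res$target_gene)
  expect_equal(back$genes, res$genes)
  expect_equal(back$status, res$status)

  # empty set -> file with only the comment header, re-read as 0 rows
  write_results(res[0, ], path)
  expect_equal(readLines(path)[1], "# gmcsr results v1 (json lines)")
  expect_equal(nrow(read_results(path)), 0)
})

test_that("timeout rows serialise with a null gene set", {
  row <- gmcsr:::gmcs_set_row("gX", character(0), NA_real_, "timeout_none",
                              FALSE, FALSE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_results(row, path)
  line <- readLines(path)[2]
  expect_match(line, '"genes":null')
  expect_equal(read_results(path)$status, "timeout_none")
})

test_that("fixtures are deterministic and feasible", {
  for (nm in c("linear_chain", "isozyme_demo", "complex_demo",
               "figure1_like")) {
    expect_gt(max_flux(make_fixture(nm)), 0)
  }
  iso <- make_fixture("isozyme_demo")
  expect_length(iso$rxns, 9)
  expect_length(iso$genes, 9)
  expect_error(make_fixture("nope"))
})

test_that("generate_random_model is seed-deterministic and feasible", {
  a <- generate_random_model(4, 8, 6, gpr_depth = 2, seed = 1)
  b <- generate_random_model(4, 8, 6, gpr_depth = 2, seed = 1)
  expect_equal(as.matrix(a$S), as.matrix(b$S), ignore_attr = TRUE)
  expect_equal(a$gpr, b$gpr)
  for (seed in c(2, 7, 13)) {
    m <- generate_random_model(3, 6, 5, gpr_depth = 1, seed = seed)
    expect_gt(max_flux(m), 0)
  }
})
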