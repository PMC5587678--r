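# Shared helpers: tiny models and set utilities used across test files.

# canonical string key for a family of gene sets (order-insensitive)
family_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# smallest valid model: one metabolite, uptake + drain (the drain is the task)
tiny_model <- function() {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r_in", "r_out")))
  metabolic_model("A", c("r_in", "r_out"), S, lb = c(0, 0),
                  ub = c(10, 10), gpr = c("", "g1"), target = "r_out",
                  id = "tiny")
}

# linear chain with an extra dead-end column appended (for FVA tests)
chain_with_dead_end <- function() {
  m <- make_fixture("linear_chain")
  S <- as.matrix(m$S)
  S <- cbind(S, dead = 0)
  S <- rbind(S, X = 0)
  S["B", "dead"] <- -1
  S["X", "dead"] <- 1   # X has no consumer: the column can never carry flux
  metabolic_model(rownames(S), colnames(S), S,
                  lb = c(m$lb, 0), ub = c(m$ub, 1000),
                  gpr = c(m$gpr, "g9"), target = m$target,
                  id = "chain_dead_end")
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
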