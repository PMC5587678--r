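#' Deterministic toy metabolic models with known answers
#'
#' Small networks used throughout the documentation and tests; every quoted
#' cut-set annotation is re-derived in the test suite by brute force, never
#' trusted. Available fixtures:
#'
#' * `"linear_chain"`: one uptake, a three-step pathway to biomass with one
#'   gene per internal reaction; every gene is a singleton cut.
#' * `"isozyme_demo"`: 9 reactions / 9 genes with an isozyme rule
#'   (`gA or gB`) on the only biomass route. The reaction-level minimal cut
#'   through that step has size 1, but at the gene level both isozymes must
#'   go: the minimal gene cut there is `{gA, gB}` — gene-minimal and
#'   reaction-minimal knockout strategies differ.
#' * `"complex_demo"`: a protein complex (`gA and gB`) on the biomass route;
#'   each subunit alone is a singleton gene cut.
#' * `"figure1_like"`: 9 reactions / 9 genes, one-to-one GPRs, two routes to
#'   the biomass precursor; with lowly expressed genes `L = {g4, g5, g9}`
#'   the set `{g2, g4, g5}` is a genetic minimal cut set, so `g2` is
#'   predicted essential in that expression context.
#'
#' @param name fixture name.
#' @return a [metabolic_model()]; `figure1_like` additionally carries the
#'   annotation attributes `"genes_L"` and `"known_gmcs"`.
#' @export
#' @examples
#' make_fixture("isozyme_demo")
make_fixture <- function(name = c("linear_chain", "isozyme_demo",
                                  "complex_demo", "figure1_like")) {
  name <- match.arg(name)
  switch(name,
    linear_chain = {
      mets <- c("A", "B", "C")
      rxns <- c("EX_A", "r1", "r2", "r_bm")
      S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
      S["A", "EX_A"] <- -1              # A <-> boundary; lb < 0 is uptake
      S["A", "r1"] <- -1; S["B", "r1"] <- 1
      S["B", "r2"] <- -1; S["C", "r2"] <- 1
      S["C", "r_bm"] <- -1
      metabolic_model(mets, rxns, S,
                      lb = c(-10, 0, 0, 0), ub = c(1000, 1000, 1000, 1000),
                      gpr = c("", "g1", "g2", "g3"),
                      target = "r_bm", id = "linear_chain")
    },
    isozyme_demo = {
      mets <- c("A", "B", "C", "D", "E", "F")
      rxns <- c("EX_A", "r1", "r2", "r3", "r4", "r_bm", "r5", "EX_F", "r6")
      S <- matrix(0, 6, 9, dimnames = list(mets, rxns))
      S["A", "EX_A"] <- -1
      S["A", "r1"] <- -1; S["B", "r1"] <- 1     # isozyme step
      S["B", "r2"] <- -1; S["C", "r2"] <- 1
      S["C", "r3"] <- -1; S["D", "r3"] <- 1     # complex step
      S["D", "r4"] <- -1; S["E", "r4"] <- 1
      S["E", "r_bm"] <- -1
      S["C", "r5"] <- -1; S["F", "r5"] <- 1     # side branch
      S["F", "EX_F"] <- -1
      S["A", "r6"] <- -1; S["F", "r6"] <- 1     # second route to F
      metabolic_model(mets, rxns, S,
                      lb = c(-10, rep(0, 8)), ub = rep(1000, 9),
                      gpr = c("", "gA or gB", "g3", "g4 and g5", "g6", "",
                              "g7", "", "g8 or g9"),
                      target = "r_bm", id = "isozyme_demo")
    },
    complex_demo = {
      mets <- c("A", "B")
      rxns <- c("EX_A", "r1", "r_bm")
      S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
      S["A", "EX_A"] <- -1
      S["A", "r1"] <- -1; S["B", "r1"] <- 1
      S["B", "r_bm"] <- -1
      metabolic_model(mets, rxns, S,
                      lb = c(-10, 0, 0), ub = rep(1000, 3),
                      gpr = c("", "gA and gB", ""),
                      target = "r_bm", id = "complex_demo")
    },
    figure1_like = {
      mets <- c("A", "B", "C", "D", "E")
      rxns <- paste0("r", 1:9)
      S <- matrix(0, 5, 9, dimnames = list(mets, rxns))
      S["A", "r1"] <- 1                          # uptake of A
      S["A", "r2"] <- -1; S["B", "r2"] <- 1      # route 1 to B
      S["A", "r3"] <- -1; S["C", "r3"] <- 1
      S["C", "r4"] <- -1; S["B", "r4"] <- 1      # route 2 to B
      S["D", "r5"] <- -1; S["B", "r5"] <- 1      # route 3 to B
      S["A", "r6"] <- -1; S["D", "r6"] <- 1
      S["B", "r7"] <- -1; S["E", "r7"] <- 1
      S["E", "r8"] <- -1                         # target task: drain E
      S["C", "r9"] <- -1; S["D", "r9"] <- 1
      m <- metabolic_model(mets, rxns, S,
                           lb = rep(0, 9), ub = rep(1000, 9),
                           gpr = paste0("g", 1:9),
                           target = "r8", id = "figure1_like")
      attr(m, "genes_L") <- c("g4", "g5", "g9")
      attr(m, "known_gmcs") <- list(c("g2", "g4", "g5"))
      m
    })
}

#' Generate a random feasible metabolic model
#'
#' Property-test input source: builds a connected network with a guaranteed
#' uptake-to-biomass backbone, adds random internal conversions, assigns
#' random AND/OR GPR trees of bounded depth, and verifies by linear
#' programming that the target reaction can carry flux before returning.
#' All randomness is fixed by `seed`; the same call returns the identical
#' model.
#'
#' @param n_mets,n_rxns,n_genes sizes (each at least 1; `n_rxns` should
#'   exceed `n_mets` to leave room for the backbone).
#' @param gpr_depth maximum nesting depth of the random GPR trees (1 =
#'   single gene or one flat AND/OR).
#' @param seed integer seed fixing all randomness.
#' @param max_tries redraw budget for the feasibility check.
#' @return a [metabolic_model()] with positive maximal target flux.
#' @export
generate_random_model <- function(n_mets, n_rxns, n_genes, gpr_depth = 2,
                                  seed = 1, max_tries = 25L) {
  stopifnot(n_mets >= 1, n_rxns >= n_mets + 2, n_genes >= 1, gpr_depth >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  for (try in seq_len(max_tries)) {
    mets <- paste0("M", seq_len(n_mets))
    rxns <- paste0("R", seq_len(n_rxns))
    S <- matrix(0, n_mets, n_rxns, dimnames = list(mets, rxns))
    ## backbone: uptake -> M1 -> ... -> Mm -> biomass drain
    S[1, 1] <- 1
    if (n_mets > 1) {
      for (k in seq_len(n_mets - 1)) S[k, k + 1] <- -1
      for (k in seq_len(n_mets - 1)) S[k + 1, k + 1] <- 1
    }
    S[n_mets, n_mets + 1] <- -1
    target <- rxns[n_mets + 1]
    ## random internal conversions
    for (j in seq(n_mets + 2, n_rxns)) {
      ns <- sample(1:2, 1); np <- sample(1:2, 1)
      sub <- sample(n_mets, min(ns, n_mets))
      cand <- setdiff(seq_len(n_mets), sub)
      pro <- cand[sample.int(length(cand), min(np, length(cand)))]
      S[sub, j] <- -1
      if (length(pro)) S[pro, j] <- 1
    }
    lb <- rep(0, n_rxns)
    ## a few reversible internals
    rev_j <- which(stats::runif(n_rxns) < 0.2)
    rev_j <- setdiff(rev_j, c(1, n_mets + 1))
    lb[rev_j] <- -10
    ub <- rep(10, n_rxns)
    gpr <- character(n_rxns)
    for (j in seq(n_mets + 2, n_rxns)) {
      gpr[j] <- gpr_deparse(random_gpr_tree(genes, gpr_depth))
    }
    ## backbone internals get single genes so cuts exist
    if (n_mets > 1) {
      for (k in seq_len(n_mets - 1)) gpr[k + 1] <- sample(genes, 1)
    }
    model <- metabolic_model(mets, rxns, S, lb, ub, gpr, genes = genes,
                             target = target,
                             id = sprintf("random_%d", seed))
    if (max_flux(model) > 1e-6) return(model)
  }
  stop("could not draw a feasible random model in ", max_tries,
       " tries; use a different seed", call. = FALSE)
}

random_gpr_tree <- function(genes, depth) {
  if (depth <= 1 || stats::runif(1) < 0.4) {
    return(list(op = "gene", id = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  args <- lapply(seq_len(k), function(i) random_gpr_tree(genes, depth - 1))
  gpr_normalize(list(op = op, args = args))
}
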