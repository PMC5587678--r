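#' Read a metabolic model from COBRA-style JSON
#'
#' The dialect follows the common constraint-based-model JSON layout:
#' top-level arrays `metabolites` (objects with `id`), `genes` (objects with
#' `id`) and `reactions` (objects with `id`, a `metabolites` map of
#' stoichiometric coefficients, `lower_bound`, `upper_bound`,
#' `gene_reaction_rule` and optionally `objective_coefficient`). The target
#' reaction is taken from `target_reaction` at the top level if present,
#' otherwise from the reaction with a non-zero `objective_coefficient`.
#'
#' @param path path to a JSON model file.
#' @param target optional target reaction id, overriding the file.
#' @return a validated [metabolic_model()].
#' @export
read_json_model <- function(path, target = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  for (fld in c("metabolites", "reactions")) {
    if (is.null(doc[[fld]])) {
      stop("model file ", path, " lacks the '", fld, "' array", call. = FALSE)
    }
  }
  mets <- vapply(doc$metabolites, function(x) as.character(x$id), character(1))
  rxn_ids <- vapply(doc$reactions, function(x) as.character(x$id), character(1))
  genes <- vapply(doc$genes %||% list(), function(x) as.character(x$id),
                  character(1))
  n <- length(rxn_ids)
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  obj_coef <- numeric(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    lb[j] <- as.numeric(r$lower_bound %||% 0)
    ub[j] <- as.numeric(r$upper_bound %||% 0)
    gpr[j] <- as.character(r$gene_reaction_rule %||% "")
    obj_coef[j] <- as.numeric(r$objective_coefficient %||% 0)
    st <- r$metabolites %||% list()
    if (length(st)) {
      idx <- match(names(st), mets)
      if (anyNA(idx)) {
        stop("reaction '", rxn_ids[j], "' references unknown metabolite '",
             names(st)[is.na(idx)][1], "'", call. = FALSE)
      }
      trip_i <- c(trip_i, idx)
      trip_j <- c(trip_j, rep(j, length(st)))
      trip_x <- c(trip_x, vapply(st, as.numeric, numeric(1)))
    }
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(mets), n))
  target <- target %||% doc$target_reaction %||%
    (if (any(obj_coef != 0)) rxn_ids[which(obj_coef != 0)[1]] else NULL)
  if (is.null(target)) {
    stop("model file ", path, " declares no target reaction; pass `target`",
         call. = FALSE)
  }
  gene_universe <- union(genes, unlist(lapply(lapply(gpr, parse_gpr),
                                              gpr_genes)))
  if (length(genes) && length(setdiff(gene_universe, genes))) {
    stop("GPR rules reference gene(s) absent from the gene list: ",
         paste(setdiff(gene_universe, genes), collapse = ", "),
         call. = FALSE)
  }
  metabolic_model(mets, rxn_ids, S, lb, ub, gpr,
                  genes = if (length(genes)) genes else NULL,
                  target = target,
                  id = as.character(doc$id %||% basename(path)))
}

#' Write a metabolic model to COBRA-style JSON
#'
#' Inverse of [read_json_model()]; the round trip is the identity.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_model <- function(model, path) {
  Sd <- as.matrix(model$S)
  reactions <- lapply(seq_along(model$rxns), function(j) {
    nz <- which(Sd[, j] != 0)
    list(id = model$rxns[j],
         metabolites = as.list(stats::setNames(Sd[nz, j], model$mets[nz])),
         lower_bound = model$lb[j], upper_bound = model$ub[j],
         gene_reaction_rule = model$gpr[j],
         objective_coefficient = as.numeric(model$rxns[j] == model$target))
  })
  doc <- list(
    id = model$id,
    metabolites = lapply(model$mets, function(m) list(id = m)),
    reactions = reactions,
    genes = lapply(model$genes, function(g) list(id = g)),
    target_reaction = model$target)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a gene-expression z-score table
#'
#' Expects a TSV with a header row; the first column holds gene (or probe)
#' ids and every remaining column one sample of z-scores. Expressed/absent
#' calls use the inclusive convention: a gene is called expressed in a
#' sample when its z-score is at least `threshold` (default 5, the
#' expression-barcode convention).
#'
#' @param path TSV path.
#' @param threshold expression-call threshold on the z-score (inclusive).
#' @return a tibble of class `expr_profile` with column `gene` and one
#'   numeric column per sample; the threshold is kept in the
#'   `"threshold"` attribute.
#' @export
read_expression_table <- function(path, threshold = 5) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) {
    stop("expression table ", path, " has no sample columns", call. = FALSE)
  }
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene row '", genes[duplicated(genes)][1],
         "' in ", path, "; aggregate probes explicitly with ",
         "aggregate_expression()", call. = FALSE)
  }
  vals <- raw[-1]
  for (cn in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[cn]]))
    bad <- which(is.na(v) & !is.na(vals[[cn]]) & nzchar(trimws(vals[[cn]])))
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop("non-numeric z-score at row ", row, " (gene '", genes[row],
           "'), column '", cn, "' of ", path, call. = FALSE)
    }
    vals[[cn]] <- v
  }
  out <- tibble::tibble(gene = genes, !!!vals)
  expr_profile(out, threshold = threshold)
}

#' Construct an expression profile from a tibble
#'
#' @param tbl tibble with a `gene` column and numeric sample columns.
#' @param threshold expression-call threshold (inclusive).
#' @return an `expr_profile` tibble.
#' @export
expr_profile <- function(tbl, threshold = 5) {
  structure(tbl, threshold = threshold,
            class = c("expr_profile", class(tibble::as_tibble(tbl))))
}

#' Expression calls of a profile
#'
#' @param profile an `expr_profile` tibble.
#' @param threshold overriding threshold; defaults to the profile's own.
#' @return tibble with `gene` and one logical column per sample
#'   (`TRUE` = expressed, i.e. z-score >= threshold).
#' @export
expression_calls <- function(profile, threshold = NULL) {
  threshold <- threshold %||% attr(profile, "threshold") %||% 5
  smp <- setdiff(names(profile), "gene")
  out <- tibble::tibble(gene = profile$gene)
  for (cn in smp) out[[cn]] <- profile[[cn]] >= threshold
  out
}

#' Write gMCS results as JSON lines
#'
#' One JSON record per result with fields `target_gene`, `genes` (sorted
#' array, `null` when no solution was found), `objective`, `status`,
#' `verified_cut` and `verified_minimal`. The first line is a `#` comment
#' header so an empty result set still produces a well-formed file.
#'
#' @param results a `gmcs_set` tibble from [enumerate_gmcs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# gmcsr results v1 (json lines)", con)
  for (i in seq_len(nrow(results))) {
    genes <- results$genes[[i]]
    rec <- list(
      target_gene = results$target_gene[i],
      genes = if (is.null(genes) || !length(genes)) NULL else sort(genes),
      objective = if (is.na(results$objective[i])) NULL else
        results$objective[i],
      status = results$status[i],
      verified_cut = results$verified_cut[i],
      verified_minimal = results$verified_minimal[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read gMCS results written by [write_results()]
#'
#' @param path JSON-lines path.
#' @return a `gmcs_set` tibble.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tibble::tibble(
      target_gene = rec$target_gene,
      genes = list(if (is.null(rec$genes)) character(0)
                   else sort(as.character(rec$genes))),
      objective = as.numeric(rec$objective %||% NA_real_),
      status = rec$status,
      verified_cut = isTRUE(rec$verified_cut),
      verified_minimal = isTRUE(rec$verified_minimal))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(target_gene = character(0), genes = list(),
                   objective = numeric(0), status = character(0),
                   verified_cut = logical(0), verified_minimal = logical(0))
  class(out) <- c("gmcs_set", class(out))
  out
}

#' Read a growth-medium table
#'
#' TSV with header `reaction`, `lower_bound`, `upper_bound`: flux bounds to
#' impose on exchange reactions (see [apply_medium()]).
#'
#' @param path TSV path.
#' @return tibble with columns `reaction`, `lower_bound`, `upper_bound`.
#' @export
read_medium_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  names(raw)[1:3] <- c("reaction", "lower_bound", "upper_bound")
  tibble::tibble(reaction = as.character(raw$reaction),
                 lower_bound = as.numeric(raw$lower_bound),
                 upper_bound = as.numeric(raw$upper_bound))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
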