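#' Aggregate probe-level expression to gene level
#'
#' When z-scores are reported per probe set, the gene-level z-score is the
#' median of its probes' z-scores (per sample); an even probe count takes
#' the midpoint of the two central values. A `consensus` column — the
#' per-gene median across samples — is appended, which is the value used
#' when one call has to represent a condition measured several times.
#'
#' @param profile an `expr_profile` tibble (first column `gene`, holding
#'   probe ids when `probe_map` is given).
#' @param probe_map optional tibble/data frame with columns `probe` and
#'   `gene` mapping probe ids to gene ids; probes missing from the map are
#'   dropped with a warning.
#' @return a gene-level `expr_profile` with an added `consensus` column.
#' @export
aggregate_expression <- function(profile, probe_map = NULL) {
  threshold <- attr(profile, "threshold") %||% 5
  smp <- setdiff(names(profile), "gene")
  tbl <- tibble::as_tibble(profile)
  if (!is.null(probe_map)) {
    probe_map <- tibble::tibble(probe = as.character(probe_map$probe),
                                gene = as.character(probe_map$gene))
    unmapped <- setdiff(tbl$gene, probe_map$probe)
    if (length(unmapped)) {
      warning("dropping ", length(unmapped),
              " probe(s) with no gene mapping: ",
              paste(utils::head(unmapped, 5), collapse = ", "),
              if (length(unmapped) > 5) ", ..." else "")
    }
    tbl <- dplyr::inner_join(tbl, probe_map,
                             by = c(gene = "probe"), suffix = c("", ".g"))
    tbl$gene <- tbl$gene.g
    tbl$gene.g <- NULL
  }
  out <- tbl |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(smp), stats::median),
                     .groups = "drop")
  out$consensus <- apply(as.matrix(out[smp]), 1, stats::median)
  expr_profile(out, threshold = threshold)
}

#' Classify lowly expressed genes (the L set)
#'
#' A gene is expressed in a sample when its z-score is at least `threshold`
#' (inclusive); genes below the threshold form the lowly expressed set `L`,
#' the knockout alphabet for genetic minimal cut sets. Genes of the model
#' that are absent from the profile are treated as expressed — an unmeasured
#' gene never licenses a cut.
#'
#' @param profile a gene-level `expr_profile`.
#' @param sample column to classify on; defaults to the single sample
#'   column, or `"consensus"` when present.
#' @param threshold z-score call threshold (default 5, inclusive).
#' @return character vector of lowly expressed gene ids.
#' @export
#' @examples
#' prof <- expr_profile(tibble::tibble(
#'   gene = c("g1", "g4", "g5", "g9"), s1 = c(8, -1, 0, 2)))
#' classify_genes(prof)   # g4, g5, g9
classify_genes <- function(profile, sample = NULL,
                           threshold = attr(profile, "threshold") %||% 5) {
  smp <- setdiff(names(profile), "gene")
  if (!length(smp)) return(character(0))
  if (is.null(sample)) {
    sample <- if ("consensus" %in% smp) "consensus" else smp[1]
  }
  if (!(sample %in% smp)) {
    stop("no sample column '", sample, "' in profile", call. = FALSE)
  }
  profile$gene[profile[[sample]] < threshold]
}

#' Classify lowly expressed reactions
#'
#' A reaction joins the lowly expressed set when its GPR rule evaluates
#' false once every gene of `genes_L` is knocked out. This single recursive
#' rule reproduces the three classification conventions for flat rules: a
#' single-gene reaction follows its gene; an OR (isozyme) rule requires all
#' of its genes in `L`; an AND (complex) rule requires any of them.
#' Reactions without gene annotation are never in `L`.
#'
#' @param model a `metabolic_model`.
#' @param genes_L character vector of lowly expressed genes.
#' @return character vector of reaction ids.
#' @export
classify_reactions <- function(model, genes_L) {
  off <- !vapply(model$rules, evaluate_gpr, logical(1), deleted = genes_L)
  model$rxns[off]
}

#' Gene and reaction L-sets for a sample
#'
#' Bundles [classify_genes()] and [classify_reactions()].
#'
#' @inheritParams classify_genes
#' @param model a `metabolic_model`.
#' @return list with `genes_L` and `reactions_L`.
#' @export
classify_lsets <- function(model, profile, sample = NULL,
                           threshold = attr(profile, "threshold") %||% 5) {
  gl <- intersect(classify_genes(profile, sample, threshold), model$genes)
  list(genes_L = gl, reactions_L = classify_reactions(model, gl))
}
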