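# GO-level aggregation of Ka/Ks results: per-term mean ratios, level-3
# category distribution of candidate vs non-candidate genes, and the
# two-step a-priori functional screen.
#
# The GO "level" of a term is 1 plus the minimum is_a path length from its
# namespace root (root = level 1); part_of edges are ignored by default.
# Gene-to-term annotation propagates upward: a gene annotated to a term
# counts for every ancestor of that term.

#' @noRd
.goGraph <- function(edges, relations = "is_a") {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  igraph::graph_from_data_frame(e[, c("child", "parent")],
                                directed = TRUE)
}

#' @noRd
.namespaceRoots <- function(edges, relations = "is_a") {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  parents <- unique(e$parent)
  setdiff(parents, e$child)
}

#' GO level of terms (minimum is_a depth below the namespace root)
#'
#' @param termIds Character vector of term ids.
#' @param edges Edge table (\code{child}, \code{parent}, \code{relation},
#'   \code{namespace}).
#' @param relations Which relations count as hierarchy edges.
#' @return Integer vector of levels (root = 1); \code{NA} for terms
#'   unreachable from any root (orphans).
#' @examples
#' onto <- toyOntology()
#' goLevel(c("GO:0008150", "GO:0006749"), onto$edges)
#' @export
goLevel <- function(termIds, edges, relations = "is_a") {
  g <- .goGraph(edges, relations)
  roots <- .namespaceRoots(edges, relations)
  known <- igraph::V(g)$name
  out <- rep(NA_integer_, length(termIds))
  present <- termIds %in% known
  if (any(present)) {
    d <- igraph::distances(g, v = termIds[present], to = roots,
                           mode = "out")
    md <- apply(d, 1, min)
    out[present] <- ifelse(is.finite(md), as.integer(md) + 1L,
                           NA_integer_)
  }
  # a root queried directly is level 1 even if it has no edges to itself
  out[termIds %in% roots] <- 1L
  out
}

# ancestors (including self) of each term id, as a named list
#' @noRd
.ancestorSets <- function(termIds, edges, relations = "is_a") {
  g <- .goGraph(edges, relations)
  known <- igraph::V(g)$name
  lapply(setNames(termIds, termIds), function(tt) {
    if (!(tt %in% known)) return(tt)
    union(tt, names(unlist(igraph::subcomponent(g, tt, mode = "out"))))
  })
}

# gene -> set of terms after upward propagation
#' @noRd
.propagatedAnnotation <- function(goAnnotation, edges,
                                  relations = "is_a") {
  anc <- .ancestorSets(unique(goAnnotation$term_id), edges, relations)
  rows <- lapply(seq_len(nrow(goAnnotation)), function(i)
    data.frame(gene_id = goAnnotation$gene_id[i],
               term_id = anc[[goAnnotation$term_id[i]]],
               stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Mean Ka/Ks per GO term
#'
#' Per term, counts the unique orthologs annotated to it (directly; no
#' upward propagation here, matching per-term means over assigned terms)
#' and averages their defined Ka/Ks ratios. Terms with fewer than
#' \code{minN} orthologs are suppressed, as are terms whose orthologs all
#' lack a defined ratio (with a warning). Output is ranked by mean ratio,
#' descending.
#'
#' @param results Results \code{data.frame} (needs \code{ref_gene_id} and
#'   \code{ratio} columns).
#' @param goAnnotation \code{data.frame} with \code{gene_id},
#'   \code{term_id}.
#' @param minN Minimum orthologs per reported term (default 10).
#' @param termNames Optional named character vector of term names.
#' @return \code{data.frame} with \code{term_id}, \code{term_name},
#'   \code{n_orthologs}, \code{n_with_ratio}, \code{mean_ratio}.
#' @export
termMeanRatio <- function(results, goAnnotation, minN = 10,
                          termNames = NULL) {
  m <- merge(goAnnotation, results[, c("ref_gene_id", "ratio")],
             by.x = "gene_id", by.y = "ref_gene_id")
  if (nrow(m) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      n_orthologs = integer(), n_with_ratio = integer(),
                      mean_ratio = numeric(), stringsAsFactors = FALSE))
  sp <- split(m, m$term_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    defined <- d$ratio[!is.na(d$ratio)]
    data.frame(term_id = d$term_id[1],
               n_orthologs = length(unique(d$gene_id)),
               n_with_ratio = length(defined),
               mean_ratio = if (length(defined)) mean(defined)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  starved <- out$n_orthologs >= minN & out$n_with_ratio == 0L
  if (any(starved))
    warning(sum(starved), " term(s) with enough orthologs but no ",
            "defined ratios suppressed")
  out <- out[out$n_orthologs >= minN & out$n_with_ratio > 0L, ,
             drop = FALSE]
  out$term_name <- if (is.null(termNames))
    rep(NA_character_, nrow(out)) else unname(termNames[out$term_id])
  out <- out[order(-out$mean_ratio, out$term_id),
             c("term_id", "term_name", "n_orthologs", "n_with_ratio",
               "mean_ratio")]
  rownames(out) <- NULL
  out
}

#' Level-rollup GO category distribution of candidates vs non-candidates
#'
#' Splits classified genes into candidates (class \code{strong} or
#' \code{candidate}, i.e. Ka/Ks > 0.5) and non-candidates (defined ratio
#' at or below 0.5); genes without a defined ratio are excluded. For each
#' term at the requested level, reports the percentage of each set
#' annotated to the term directly or via any descendant. Percentages can
#' sum over 100 across terms because genes carry multiple annotations.
#'
#' @param results Results \code{data.frame} with \code{ref_gene_id},
#'   \code{ratio} and \code{class} columns.
#' @param goAnnotation Gene-to-term table.
#' @param edges GO edge table.
#' @param level GO level of the reporting terms (default 3).
#' @param termNames Optional named term-name vector.
#' @return \code{data.frame} with \code{term_id}, \code{term_name},
#'   \code{level}, \code{n_candidate}, \code{n_noncandidate},
#'   \code{pct_candidate}, \code{pct_noncandidate} and
#'   \code{candidate_enriched} (candidate \% strictly above
#'   non-candidate \%).
#' @export
categoryDistribution <- function(results, goAnnotation, edges,
                                 level = 3, termNames = NULL) {
  cls <- results$class
  cand <- unique(results$ref_gene_id[cls %in% c("strong", "candidate")])
  nonc <- unique(results$ref_gene_id[cls == "non_candidate"])
  cand <- cand[!is.na(cand)]
  nonc <- setdiff(nonc[!is.na(nonc)], cand)
  prop <- .propagatedAnnotation(goAnnotation, edges)
  lev <- goLevel(unique(prop$term_id), edges)
  atLevel <- unique(prop$term_id)[!is.na(lev) & lev == level]
  out <- do.call(rbind, lapply(atLevel, function(tt) {
    genes <- prop$gene_id[prop$term_id == tt]
    nc <- sum(cand %in% genes)
    nn <- sum(nonc %in% genes)
    data.frame(term_id = tt,
               level = level,
               n_candidate = nc, n_noncandidate = nn,
               pct_candidate = if (length(cand)) 100 * nc / length(cand)
                               else 0,
               pct_noncandidate = if (length(nonc))
                 100 * nn / length(nonc) else 0,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(term_id = character(), level = integer(),
                      n_candidate = integer(), n_noncandidate = integer(),
                      pct_candidate = numeric(),
                      pct_noncandidate = numeric(),
                      stringsAsFactors = FALSE)
  out$candidate_enriched <- out$pct_candidate > out$pct_noncandidate
  out$term_name <- if (is.null(termNames))
    rep(NA_character_, nrow(out)) else unname(termNames[out$term_id])
  out <- out[order(-out$pct_candidate, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Two-step a-priori functional screen of candidate genes
#'
#' Step 1 matches candidate genes against a hypoxia/oxygen-related term
#' list (after Simonson and colleagues' high-altitude candidate
#' functions); step 2 against functions proposed for poikilotherm
#' high-elevation adaptation (UV response, reactive-oxygen metabolism,
#' metabolic regulation). A gene matches a listed term when any of its
#' annotated terms equals the listed term or descends from it. Term ids
#' absent from the edge table trigger a warning and are skipped (they
#' still match direct annotations).
#'
#' @param results Results \code{data.frame} with \code{pair_id},
#'   \code{ref_gene_id}, \code{ratio}, \code{class}.
#' @param goAnnotation Gene-to-term table.
#' @param step1Terms,step2Terms Character vectors of GO ids (defaults
#'   ship with the package; see [defaultScreenTerms()]).
#' @param edges GO edge table (needed for descendant matching; optional).
#' @return \code{data.frame} with \code{pair_id}, \code{ref_gene_id},
#'   \code{ratio}, \code{class}, \code{matched_term}, \code{step}
#'   (\code{hypoxia_list} / \code{poikilotherm_list}), deduplicated.
#' @export
functionalScreen <- function(results, goAnnotation,
                             step1Terms = defaultScreenTerms("hypoxia"),
                             step2Terms = defaultScreenTerms("poikilotherm"),
                             edges = NULL) {
  cand <- results[results$class %in% c("strong", "candidate"), ,
                  drop = FALSE]
  empty <- data.frame(pair_id = character(), ref_gene_id = character(),
                      ratio = numeric(), class = character(),
                      matched_term = character(), step = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) return(empty)
  ann <- if (is.null(edges)) goAnnotation
         else .propagatedAnnotation(goAnnotation, edges)
  if (!is.null(edges)) {
    known <- unique(c(edges$child, edges$parent))
    for (lst in list(step1 = step1Terms, step2 = step2Terms)) {
      unknown <- setdiff(lst, c(known, goAnnotation$term_id))
      if (length(unknown))
        warning("screen list term(s) not in the ontology skipped: ",
                paste(unknown, collapse = ", "))
    }
    step1Terms <- intersect(step1Terms, c(known, goAnnotation$term_id))
    step2Terms <- intersect(step2Terms, c(known, goAnnotation$term_id))
  }
  steps <- list(hypoxia_list = step1Terms,
                poikilotherm_list = step2Terms)
  rows <- list()
  for (stepName in names(steps)) {
    hits <- ann[ann$term_id %in% steps[[stepName]], , drop = FALSE]
    m <- cand[cand$ref_gene_id %in% hits$gene_id, , drop = FALSE]
    for (i in seq_len(nrow(m))) {
      terms <- hits$term_id[hits$gene_id == m$ref_gene_id[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = m$pair_id[i], ref_gene_id = m$ref_gene_id[i],
        ratio = m$ratio[i], class = m$class[i],
        matched_term = terms, step = stepName,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}

#' Default a-priori GO term lists for the two-step screen
#'
#' The hypoxia list carries oxygen-transport and hypoxia-response terms;
#' the poikilotherm list carries UV-response, reactive-oxygen and
#' metabolic terms. Both are plain TSV files under the package's
#' \code{extdata} and can be replaced by the user's own lists.
#'
#' @param which \code{"hypoxia"} (step 1) or \code{"poikilotherm"}
#'   (step 2).
#' @return Character vector of GO term ids.
#' @export
defaultScreenTerms <- function(which = c("hypoxia", "poikilotherm")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("go_", which, "_terms.tsv"),
                   package = "kaksScreen", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)$term_id
}
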