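#' Species delimitation configuration
#'
#' Thresholds for distance-based species hypotheses on COI barcodes.
#'
#' @param t_high Heterospecific threshold: species-pair mean divergence above
#'   this supports heterospecificity on its own (default 0.03, the
#'   conventional "over 3%" barcode rule).
#' @param t_low Floor of the grey zone: divergence in `(t_low, t_high]`
#'   supports heterospecificity only together with (even subtle) genitalic
#'   differences (default 0.02, the "as little as 2%" case).
#' @param near_identical Conspecific ceiling: pairs at or below this mean
#'   divergence that also share detailed genital morphology are conspecific
#'   (default 0.005; the rule is verbal in barcode practice, quantified here
#'   and configurable).
#' @param ratio_min Barcoding-gap factor: interspecific must exceed
#'   intraspecific divergence by at least this ratio (default 10).
#' @param linkage Clustering linkage for OTUs; only `"single"` is supported
#'   (the threshold language concerns any-to-any divergence).
#' @return A list of class `delim_config`.
#' @export
delim_config <- function(t_high = 0.03, t_low = 0.02, near_identical = 0.005,
                         ratio_min = 10, linkage = "single") {
  stopifnot(t_high > 0, t_high < 1, t_low > 0, near_identical > 0)
  if (!(near_identical <= t_low && t_low <= t_high))
    stop("need near_identical <= t_low <= t_high")
  if (ratio_min <= 1) stop("ratio_min must be > 1")
  if (!identical(linkage, "single"))
    stop("only single linkage is supported")
  structure(list(t_high = t_high, t_low = t_low,
                 near_identical = near_identical, ratio_min = ratio_min,
                 linkage = linkage),
            class = "delim_config")
}

#' Barcoding-gap report
#'
#' Per-species gap statistics: the maximum intraspecific pairwise distance,
#' the minimum distance from any individual of the species to any individual
#' of another species, and their ratio `min_inter / max_intra` (the
#' barcoding gap in its standard extreme-value form; `Inf` when
#' `max_intra = 0`, `NA` for singletons). Mean-based analogues (mean
#' intraspecific distance and smallest among-species mean) are reported
#' alongside, since divergence tables are usually discussed at that
#' granularity. Undefined distances are excluded throughout.
#'
#' @param m A `barcode_dist`.
#' @param species_of Named vector mapping record id to species.
#' @param cfg A [delim_config()].
#' @return Object of class `gap_report`: data frame (one row per species)
#'   with columns `species`, `n`, `max_intra`, `min_inter`, `ratio`,
#'   `mean_intra`, `min_among_mean`, `mean_ratio`, `pass`; attribute
#'   `all_pass` is `TRUE` when every multi-individual species passes
#'   `ratio >= ratio_min`.
#' @export
barcode_gap_report <- function(m, species_of, cfg = delim_config()) {
  stopifnot(inherits(m, "barcode_dist"))
  sp <- species_of[m$labels]
  if (anyNA(sp))
    stop("unknown species for record(s): ", m$labels[is.na(sp)][1])
  species <- sort(unique(unname(sp)))
  if (length(species) < 2L) stop("need at least 2 species")
  summ <- species_distance_summary(m, species_of)
  rows <- lapply(species, function(s) {
    ri <- which(sp == s); rj <- which(sp != s)
    n <- length(ri)
    max_intra <- mean_intra <- NA_real_
    if (n >= 2L) {
      v <- m$d[ri, ri][upper.tri(diag(n))]
      if (any(!is.na(v))) {
        max_intra <- max(v, na.rm = TRUE)
        mean_intra <- mean(v, na.rm = TRUE)
      }
    }
    vx <- as.vector(m$d[ri, rj, drop = FALSE])
    min_inter <- if (any(!is.na(vx))) min(vx, na.rm = TRUE) else NA_real_
    am <- summ$among[s, setdiff(species, s)]
    min_among_mean <- if (any(!is.na(am))) min(am, na.rm = TRUE) else NA_real_
    ratio <- if (is.na(max_intra) || is.na(min_inter)) NA_real_
             else if (max_intra == 0) Inf else min_inter / max_intra
    mean_ratio <- if (is.na(mean_intra) || is.na(min_among_mean)) NA_real_
                  else if (mean_intra == 0) Inf else min_among_mean / mean_intra
    data.frame(species = s, n = n, max_intra = max_intra,
               min_inter = min_inter, ratio = ratio,
               mean_intra = mean_intra, min_among_mean = min_among_mean,
               mean_ratio = mean_ratio,
               pass = if (is.na(ratio)) NA else ratio >= cfg$ratio_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  multi <- out$n >= 2L & !is.na(out$pass)
  structure(out, class = c("gap_report", "data.frame"),
            all_pass = all(out$pass[multi]), config = cfg)
}

#' Threshold-based OTU clustering (single linkage)
#'
#' Connected components of the graph joining record pairs whose distance is
#' at or below `threshold`. Undefined distances never merge clusters. When
#' species labels are supplied, each species is scored `"concordant"` (its
#' records form exactly one cluster containing no other species),
#' `"split"` (records spread over several clusters) or `"lumped"` (single
#' cluster shared with another species).
#'
#' @param m A `barcode_dist`.
#' @param threshold Distance threshold, >= 0.
#' @param species_of Optional named vector mapping record id to species.
#' @return Object of class `otu_partition`: list with `threshold`,
#'   `membership` (named integer vector, cluster ids renumbered by first
#'   appearance), `clusters` (list of id vectors), `concordance` (data
#'   frame, or `NULL`).
#' @export
threshold_otus <- function(m, threshold, species_of = NULL) {
  stopifnot(inherits(m, "barcode_dist"), threshold >= 0)
  n <- length(m$labels)
  adj <- !is.na(m$d) & m$d <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))  # renumber by first appearance
  names(memb) <- m$labels
  clusters <- split(m$labels, memb)
  concordance <- NULL
  if (!is.null(species_of)) {
    sp <- species_of[m$labels]
    if (anyNA(sp)) stop("unknown species for record(s): ",
                        m$labels[is.na(sp)][1])
    cl_species <- split(unname(sp), memb)
    concordance <- do.call(rbind, lapply(sort(unique(unname(sp))), function(s) {
      cls <- unique(memb[sp == s])
      status <- if (length(cls) > 1L) "split"
                else if (length(unique(cl_species[[as.character(cls)]])) > 1L) "lumped"
                else "concordant"
      data.frame(species = s, n_clusters = length(cls), status = status,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(threshold = threshold, membership = memb,
                 clusters = clusters, concordance = concordance),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("otu_partition: %d records in %d cluster(s) at threshold %g\n",
              length(x$membership), length(x$clusters), x$threshold))
  invisible(x)
}

#' Rule-based species-pair delimitation decisions
#'
#' Applies the delimitation rules to every species pair, using the pair's
#' among-group mean distance `d`:
#' \enumerate{
#'   \item `d <= near_identical` and shared morphology -> `"conspecific"`;
#'   \item `d > t_high` and morphology absent or different ->
#'     `"heterospecific"` (the over-3% rule);
#'   \item `t_low < d <= t_high` and genitalic differences ->
#'     `"heterospecific"` (the as-little-as-2% rule);
#'   \item otherwise `"ambiguous"` (requires morphology).
#' }
#' Pairs with no defined distance are `"ambiguous"`. Decisions operate on
#' among-species means, the granularity of the divergence table; extreme
#' value (any-to-any) behaviour remains visible via [threshold_otus()].
#'
#' @param m A `barcode_dist`.
#' @param species_of Named vector mapping record id to species.
#' @param morphology Optional data frame with columns `species_a`,
#'   `species_b`, `genitalic_difference` (logical); order of the pair does
#'   not matter. Pairs not listed are treated as lacking morphological data.
#' @param cfg A [delim_config()].
#' @return Data frame with columns `species_a`, `species_b`, `mean_d`,
#'   `decision`, `rule`.
#' @export
delimit <- function(m, species_of, morphology = NULL, cfg = delim_config()) {
  summ <- species_distance_summary(m, species_of)
  species <- summ$species
  if (!is.null(morphology)) {
    stopifnot(all(c("species_a", "species_b", "genitalic_difference") %in%
                    names(morphology)))
    unknown <- setdiff(c(morphology$species_a, morphology$species_b), species)
    if (length(unknown))
      stop("morphology table references unknown species: ",
           paste(unknown, collapse = ", "))
  }
  morph_of <- function(a, b) {
    if (is.null(morphology)) return(NA)
    hit <- (morphology$species_a == a & morphology$species_b == b) |
           (morphology$species_a == b & morphology$species_b == a)
    if (!any(hit)) NA else morphology$genitalic_difference[which(hit)[1]]
  }
  out <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (j <= i) next
    a <- species[i]; b <- species[j]
    d <- summ$among[a, b]
    morph_diff <- morph_of(a, b)
    if (is.na(d)) {
      dec <- "ambiguous"; rule <- "no defined distance"
    } else if (d <= cfg$near_identical && isFALSE(morph_diff)) {
      dec <- "conspecific"
      rule <- sprintf("near-identical barcodes (d <= %g) + shared morphology",
                      cfg$near_identical)
    } else if (d > cfg$t_high && (is.na(morph_diff) || isTRUE(morph_diff))) {
      dec <- "heterospecific"
      rule <- sprintf("divergence > %g%%", 100 * cfg$t_high)
    } else if (d > cfg$t_low && d <= cfg$t_high && isTRUE(morph_diff)) {
      dec <- "heterospecific"
      rule <- sprintf("divergence > %g%% with genitalic differences",
                      100 * cfg$t_low)
    } else {
      dec <- "ambiguous"; rule <- "requires morphology"
    }
    out[[length(out) + 1L]] <-
      data.frame(species_a = a, species_b = b, mean_d = d,
                 decision = dec, rule = rule, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a gap report as JSON or TSV
#'
#' @param report A `gap_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gap_report_json <- function(report, path) {
  payload <- list(per_species = as.data.frame(report),
                  all_multi_individual_pass = attr(report, "all_pass"),
                  config = unclass(attr(report, "config")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_gap_report_json
#' @export
write_gap_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an OTU partition as two-column TSV
#'
#' @param otus An `otu_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_tsv <- function(otus, path) {
  utils::write.table(
    data.frame(record_id = names(otus$membership),
               cluster = unname(otus$membership)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
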