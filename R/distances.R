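#' Distance model configuration
#'
#' @param model Substitution model: `"tn93"` (default), `"k2p"`, `"jc69"` or
#'   `"p"` (raw proportion of differing sites).
#' @param gamma_shape Shape `alpha` of the gamma distribution of among-site
#'   rate variation, or `NULL` for no rate heterogeneity. Default 1. The
#'   corrected distance decreases monotonically toward the uncorrected value
#'   as `alpha` grows. Ignored for `model = "p"`.
#' @param min_overlap Minimum number of jointly observed unambiguous sites
#'   for a pair's distance to be defined (default 100). Pairs below this are
#'   flagged undefined (`NA`) rather than reported.
#' @details Distances are always computed with pairwise deletion: each pair
#'   is compared over the sites observed unambiguously in both sequences.
#'   IUPAC ambiguity codes are excluded from the comparison (treated as
#'   missing), not resolved fractionally. Saturated pairs (any logarithm
#'   argument <= 0) are undefined rather than clamped.
#' @return A list of class `dist_model_config`.
#' @export
dist_config <- function(model = c("tn93", "k2p", "jc69", "p"),
                        gamma_shape = 1, min_overlap = 100L) {
  model <- match.arg(model)
  if (!is.null(gamma_shape)) {
    stopifnot(is.numeric(gamma_shape), length(gamma_shape) == 1L)
    if (gamma_shape <= 0) stop("gamma_shape must be > 0 (or NULL)")
  }
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L) stop("min_overlap must be >= 1")
  structure(list(model = model, gamma_shape = gamma_shape,
                 min_overlap = min_overlap, deletion = "pairwise"),
            class = "dist_model_config")
}

# Gamma-corrected analogue of -log(w): alpha * (w^(-1/alpha) - 1).
# With alpha = NULL this is plain -log(w). Vectorized; w <= 0 gives NA
# (saturation, distance undefined).
.log_term <- function(w, alpha) {
  w <- ifelse(!is.na(w) & w > 0, w, NA_real_)  # saturation -> undefined
  if (is.null(alpha)) -log(w) else alpha * (w^(-1 / alpha) - 1)
}

# Distance from sufficient statistics. All arguments may be equal-length
# vectors (or matrices). p1 = A<->G transition proportion, p2 = C<->T,
# q = transversion proportion, freqs = list(A=,C=,G=,T=) of pair base
# frequencies (only used by tn93).
.dist_from_counts <- function(model, alpha, p_mismatch, p1, p2, q, freqs) {
  switch(model,
    p = p_mismatch,
    jc69 = 0.75 * .log_term(1 - 4 * p_mismatch / 3, alpha),
    k2p = {
      P <- p1 + p2
      0.5 * .log_term(1 - 2 * P - q, alpha) + 0.25 * .log_term(1 - 2 * q, alpha)
    },
    tn93 = {
      gA <- freqs$A; gC <- freqs$C; gG <- freqs$G; gT <- freqs$T
      gR <- gA + gG; gY <- gC + gT
      k1 <- 2 * gA * gG / gR
      k2 <- 2 * gT * gC / gY
      k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
      t1 <- .log_term(1 - p1 / k1 - q / (2 * gR), alpha)
      t2 <- .log_term(1 - p2 / k2 - q / (2 * gY), alpha)
      t3 <- .log_term(1 - q / (2 * gR * gY), alpha)
      # degenerate pairs with no purines (or no pyrimidines) observed have
      # k = 0 and necessarily p = 0 there; the term's limit is 0
      t1 <- ifelse(k1 == 0 & p1 == 0, 0, t1)
      t2 <- ifelse(k2 == 0 & p2 == 0, 0, t2)
      k1 * ifelse(k1 == 0, 0, t1) + k2 * ifelse(k2 == 0, 0, t2) + k3 * t3
    },
    stop("unknown model '", model, "'"))
}

#' Pairwise genetic distance between two aligned barcode sequences
#'
#' Computes the distance over the jointly observed unambiguous sites only
#' (pairwise deletion; ambiguity codes are excluded). `p` is the raw
#' proportion of differing sites; `jc69`, `k2p` and `tn93` apply the
#' Jukes-Cantor, Kimura two-parameter and Tamura-Nei closed forms, the
#' latter with base frequencies estimated from the pair itself. With a
#' finite `gamma_shape` alpha every logarithmic term `-log(w)` is replaced
#' by its gamma counterpart `alpha * (w^(-1/alpha) - 1)`.
#'
#' @param a,b Character vectors of aligned IUPAC symbols (equal length), or
#'   single strings.
#' @param cfg A [dist_config()].
#' @return A non-negative number, or `NA` when the pair's overlap is below
#'   `cfg$min_overlap` or the model correction is saturated.
#' @export
#' @examples
#' pairwise_distance("ACGT", "ACGA", dist_config("p", min_overlap = 1))
pairwise_distance <- function(a, b, cfg = dist_config()) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  a <- toupper(a); b <- toupper(b)
  if (length(a) != length(b))
    stop("alignment mismatch: sequences have lengths ",
         length(a), " and ", length(b))
  joint <- .is_base(a) & .is_base(b)
  n <- sum(joint)
  if (n < cfg$min_overlap) return(NA_real_)
  aj <- a[joint]; bj <- b[joint]
  diff <- aj != bj
  ts1 <- sum((aj == "A" & bj == "G") | (aj == "G" & bj == "A"))
  ts2 <- sum((aj == "C" & bj == "T") | (aj == "T" & bj == "C"))
  q <- sum(diff) - ts1 - ts2
  freqs <- lapply(DNA_BASES, function(x) (sum(aj == x) + sum(bj == x)) / (2 * n))
  names(freqs) <- DNA_BASES
  d <- .dist_from_counts(cfg$model, cfg$gamma_shape,
                         sum(diff) / n, ts1 / n, ts2 / n, q / n, freqs)
  as.numeric(d)
}

#' All-pairs distance matrix for a barcode alignment
#'
#' Vectorized over indicator matrices so that the sufficient statistics of
#' every pair (overlap, transition and transversion counts, pair base
#' frequencies) come from a handful of matrix products; identical, to
#' machine precision, to calling [pairwise_distance()] on every pair.
#'
#' @param aln A `barcode_alignment` with at least 2 records.
#' @param cfg A [dist_config()].
#' @return An object of class `barcode_dist`: list with `labels`, `d`
#'   (symmetric numeric matrix, zero diagonal, `NA` for undefined pairs),
#'   `n_undefined` (count of undefined off-diagonal pairs), `model`,
#'   `gamma_shape`, `min_overlap`.
#' @export
distance_matrix <- function(aln, cfg = dist_config()) {
  stopifnot(inherits(aln, "barcode_alignment"))
  n <- n_records(aln)
  if (n < 2L) stop("need at least 2 records")
  S <- aln$seq
  Ib <- lapply(DNA_BASES, function(b) (S == b) * 1)
  names(Ib) <- DNA_BASES
  obs <- Reduce(`+`, Ib)
  overlap <- obs %*% t(obs)
  match <- Reduce(`+`, lapply(Ib, function(M) M %*% t(M)))
  AG <- Ib$A %*% t(Ib$G); ts1 <- AG + t(AG)
  CT <- Ib$C %*% t(Ib$T); ts2 <- CT + t(CT)
  mism <- overlap - match
  q <- mism - ts1 - ts2
  defined <- overlap >= cfg$min_overlap
  ov <- ifelse(defined, overlap, NA_real_)
  freqs <- lapply(Ib, function(M) {
    F <- M %*% t(obs)
    (F + t(F)) / (2 * ov)
  })
  d <- .dist_from_counts(cfg$model, cfg$gamma_shape,
                         mism / ov, ts1 / ov, ts2 / ov, q / ov, freqs)
  d[!defined] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(aln$id, aln$id)
  barcode_dist(d, aln$id, model = cfg$model, gamma_shape = cfg$gamma_shape,
               min_overlap = cfg$min_overlap)
}

#' Construct a `barcode_dist` object from a symmetric matrix
#'
#' Mostly used internally and in tests; validates symmetry, a zero diagonal
#' and non-negative defined entries.
#'
#' @param d Symmetric numeric matrix (`NA` marks undefined pairs).
#' @param labels Record identifiers.
#' @param model,gamma_shape,min_overlap Provenance fields (optional).
#' @return A `barcode_dist` object.
#' @export
barcode_dist <- function(d, labels = rownames(d), model = "unspecified",
                         gamma_shape = NULL, min_overlap = NA_integer_) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0, na.rm = TRUE)) stop("diagonal must be exactly 0")
  if (any(d < 0, na.rm = TRUE)) stop("defined distances must be >= 0")
  dimnames(d) <- list(labels, labels)
  structure(list(labels = as.character(labels), d = d,
                 n_undefined = sum(is.na(d[upper.tri(d)])),
                 model = model, gamma_shape = gamma_shape,
                 min_overlap = min_overlap),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("barcode_dist: %d records, model %s%s, %d undefined pair(s)\n",
              length(x$labels), x$model,
              if (is.null(x$gamma_shape)) "" else
                sprintf(" (gamma alpha = %g)", x$gamma_shape),
              x$n_undefined))
  invisible(x)
}

#' Within- and among-species distance averages
#'
#' Arithmetic averages of the defined pairwise distances, at the granularity
#' of the classic divergence table: one intraspecific mean per species
#' (`NA` for single-individual species or species with no defined pair,
#' printed as "n/a"), a symmetric species-by-species among-group mean
#' matrix, and the grand mean of the intraspecific means.
#'
#' @param m A `barcode_dist`.
#' @param species_of Named character vector mapping every record id to its
#'   species label.
#' @return An object of class `species_dist_summary`: list with `species`,
#'   `intraspecific` (named vector), `among` (matrix), `overall_intraspecific`,
#'   `n_records` (per species), `n_undefined_pairs`.
#' @export
species_distance_summary <- function(m, species_of) {
  stopifnot(inherits(m, "barcode_dist"))
  sp <- species_of[m$labels]
  if (anyNA(sp))
    stop("unknown species for record(s): ",
         paste(m$labels[is.na(sp)][1], collapse = ", "))
  species <- sort(unique(unname(sp)))
  S <- length(species)
  intra <- stats::setNames(rep(NA_real_, S), species)
  among <- matrix(NA_real_, S, S, dimnames = list(species, species))
  for (i in seq_len(S)) {
    ri <- which(sp == species[i])
    if (length(ri) >= 2L) {
      v <- m$d[ri, ri][upper.tri(diag(length(ri)))]
      if (any(!is.na(v))) intra[i] <- mean(v, na.rm = TRUE)
    }
    for (j in seq_len(S)) {
      if (j >= i) next
      rj <- which(sp == species[j])
      v <- as.vector(m$d[ri, rj, drop = FALSE])
      if (any(!is.na(v))) {
        among[i, j] <- among[j, i] <- mean(v, na.rm = TRUE)
      }
    }
  }
  structure(list(species = species, intraspecific = intra, among = among,
                 overall_intraspecific =
                   if (all(is.na(intra))) NA_real_ else mean(intra, na.rm = TRUE),
                 n_records = table(factor(unname(sp), levels = species)),
                 n_undefined_pairs = m$n_undefined),
            class = "species_dist_summary")
}

#' @export
print.species_dist_summary <- function(x, digits = 3, ...) {
  cat(sprintf("species_dist_summary: %d species, overall intraspecific mean %s\n",
              length(x$species),
              format(round(x$overall_intraspecific, digits))))
  invisible(x)
}

#' Write a square distance matrix as TSV
#'
#' @param m A `barcode_dist`.
#' @param path Output path. Undefined entries are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(id = m$labels, m$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Format a species distance summary as a divergence table
#'
#' Lower-triangle among-species means with a leading intraspecific column;
#' undefined entries are the literal `"n/a"`. Values rounded to `digits`
#' decimals for display (3, matching the conventional table precision).
#'
#' @param s A `species_dist_summary`.
#' @param digits Decimal places (default 3).
#' @return A character data frame.
#' @export
format_species_summary <- function(s, digits = 3) {
  S <- length(s$species)
  fmt <- function(v) ifelse(is.na(v), "n/a", formatC(round(v, digits),
                                                     format = "f", digits = digits))
  tri <- matrix("", S, S)
  for (i in seq_len(S)) for (j in seq_len(S))
    if (j < i) tri[i, j] <- fmt(s$among[i, j]) else if (j == i) tri[i, j] <- "X"
  out <- data.frame(index = seq_len(S), species = s$species,
                    intraspecific = fmt(s$intraspecific), tri,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[-(1:3)] <- as.character(seq_len(S))
  out
}

#' @rdname format_species_summary
#' @param path Output CSV path.
#' @export
write_species_summary_csv <- function(s, path, digits = 3) {
  utils::write.csv(format_species_summary(s, digits), path, row.names = FALSE)
  invisible(path)
}
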