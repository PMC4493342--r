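#' Simulation configuration for species-structured barcode alignments
#'
#' Defaults emulate the empirical setting the package targets: 16 species
#' with 1 to ~100 individuals each (four singletons, the densest species
#' near 100, ~330 barcodes in total), 1011 aligned COI-like positions
#' anchored at base 1 of the standard barcode, among-species divergence
#' 2-16%, intraspecific pairwise divergence ~0.2%, a handful of planted
#' diagnostic sites per species, one singleton species observed only from
#' position 824 onward, and occasional IUPAC ambiguities.
#'
#' @param n_species Number of species (default 16).
#' @param n_individuals Integer vector of individuals per species (recycled
#'   or length `n_species`), or a length-2 range `c(lo, hi)` sampled
#'   uniformly per species when `n_species != 2`.
#' @param seq_length Alignment columns (default 1011).
#' @param divergence Range of target pairwise among-species divergence
#'   (default `c(0.02, 0.16)`); species branch divergences are drawn
#'   uniformly from half this range so pair sums land in it.
#' @param intra_rate Per-site, per-individual mutation probability away from
#'   the species consensus (default 0.001, i.e. expected pairwise
#'   intraspecific divergence ~0.2%). Realized as an exact per-individual
#'   mutation count `round(intra_rate * n_mutable)` so that planted
#'   divergences stay controlled.
#' @param n_unique_sites Planted unique diagnostic sites per species
#'   (default 5).
#' @param n_shared_sites Planted partially shared diagnostic sites per
#'   species (default 3).
#' @param max_sharers Maximum sharers per planted shared site (default 2).
#' @param truncate_species Index of one species whose records are all
#'   observed only from `truncation_start` onward (default 1, a singleton
#'   under the default `n_individuals`; 0 disables truncation). That
#'   species' planted sites are placed at or beyond `truncation_start`.
#' @param truncation_start First observed reference position of truncated
#'   records (default 824).
#' @param truncated_fraction Additional fraction of records, over all
#'   species, truncated at `truncation_start` (default 0).
#' @param ambiguity_rate Probability that an observed, non-planted site of a
#'   record is replaced by a two-fold IUPAC ambiguity covering its base
#'   (default 0.001). Planted sites are never made ambiguous so that the
#'   planted truth stays exactly recoverable.
#' @param species_names Optional character vector of species labels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 16L,
                       n_individuals = c(1L, 1L, 1L, 1L, 3L, 5L, 8L, 10L, 14L,
                                         18L, 22L, 28L, 34L, 40L, 48L, 97L),
                       seq_length = 1011L,
                       divergence = c(0.02, 0.16),
                       intra_rate = 0.001,
                       n_unique_sites = 5L,
                       n_shared_sites = 3L,
                       max_sharers = 2L,
                       truncate_species = 1L,
                       truncation_start = 824L,
                       truncated_fraction = 0,
                       ambiguity_rate = 0.001,
                       species_names = NULL) {
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 1L, seq_length >= 1L)
  stopifnot(length(divergence) == 2L, divergence[1] >= 0,
            divergence[2] >= divergence[1], divergence[2] < 0.75)
  stopifnot(intra_rate >= 0, intra_rate <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            truncated_fraction >= 0, truncated_fraction <= 1)
  if (length(n_individuals) == 2L && n_species != 2L) {
    n_individuals <- as.integer(n_individuals)  # range, sampled at run time
  } else {
    n_individuals <- as.integer(rep_len(n_individuals, n_species))
  }
  if (is.null(species_names))
    species_names <- sprintf("sim_species_%02d", seq_len(n_species))
  stopifnot(length(species_names) == n_species || length(n_individuals) == 2L)
  structure(list(n_species = n_species, n_individuals = n_individuals,
                 seq_length = as.integer(seq_length), divergence = divergence,
                 intra_rate = intra_rate,
                 n_unique_sites = as.integer(n_unique_sites),
                 n_shared_sites = as.integer(n_shared_sites),
                 max_sharers = as.integer(max_sharers),
                 truncate_species = as.integer(truncate_species),
                 truncation_start = as.integer(truncation_start),
                 truncated_fraction = truncated_fraction,
                 ambiguity_rate = ambiguity_rate,
                 species_names = species_names),
            class = "sim_config")
}

# sample() without the scalar-x surprise: draws n elements of x itself
.sample_from <- function(x, n) x[sample.int(length(x), n)]

# random base different from `from`, uniform over the 3 alternatives
.mutate_base <- function(from) {
  vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a species-structured barcode alignment with planted truth
#'
#' Species consensus sequences descend from a random ancestor on a star
#' phylogeny: each species mutates an exact number of sites
#' (`round(branch_divergence * seq_length)`, minus its planted-site budget)
#' at site sets disjoint across species, so realized pairwise consensus
#' divergences are controlled rather than binomially noisy. Planted unique
#' and shared diagnostic sites are then overwritten to guarantee the
#' uniqueness/sharing structure recorded in the returned truth. Individuals
#' carry an exact number of private mutations at non-planted sites;
#' truncation and ambiguity injection are applied last and never touch
#' planted sites. Identical `(cfg, seed)` gives bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (mandatory; RNG state is restored on exit).
#' @return List with `alignment` (a [barcode_alignment()]) and `truth`
#'   (class `synthetic_truth`): planted unique/shared sites per species,
#'   branch divergences, per-pair expected p-distance (`expected_pairwise`),
#'   per-individual mutation count `m_intra`, seed and generator version.
#' @export
simulate_alignment <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  withr::with_seed(as.integer(seed), .simulate_impl(cfg, as.integer(seed)))
}

.simulate_impl <- function(cfg, seed) {
  S <- cfg$n_species
  L <- cfg$seq_length
  n_ind <- cfg$n_individuals
  if (length(n_ind) == 2L && S != 2L)
    n_ind <- sample(seq(n_ind[1], n_ind[2]), S, replace = TRUE)
  species <- cfg$species_names
  u <- cfg$n_unique_sites; s_sites <- cfg$n_shared_sites
  per_sp_planted <- u + s_sites
  if (per_sp_planted * S > L)
    stop("infeasible config: more planted sites (", per_sp_planted * S,
         ") than alignment positions (", L, ")")
  if (cfg$max_sharers > 3L && s_sites > 0L)
    stop("infeasible config: a site state cannot exclude more than 3 ",
         "alternative states with a 4-letter alphabet")
  trunc_sp <- cfg$truncate_species
  do_trunc <- trunc_sp >= 1L && trunc_sp <= S && cfg$truncation_start > 1L
  if (do_trunc && cfg$truncation_start > L)
    stop("infeasible config: truncation_start beyond the alignment")
  if (do_trunc && per_sp_planted > L - cfg$truncation_start + 1L)
    stop("infeasible config: truncated species cannot host its planted ",
         "sites beyond truncation_start")

  # --- planted positions, distinct across species -------------------------
  pool <- seq_len(L)
  planted <- vector("list", S)
  if (do_trunc && per_sp_planted > 0L) {
    tail_pool <- pool[pool >= cfg$truncation_start]
    planted[[trunc_sp]] <- sort(.sample_from(tail_pool, per_sp_planted))
    pool <- setdiff(pool, planted[[trunc_sp]])
  }
  for (i in seq_len(S)) {
    if (i == trunc_sp && do_trunc) next
    if (per_sp_planted > 0L) {
      planted[[i]] <- sort(.sample_from(pool, per_sp_planted))
      pool <- setdiff(pool, planted[[i]])
    } else planted[[i]] <- integer()
  }
  all_planted <- sort(unlist(planted))

  # --- ancestor and planted states ----------------------------------------
  anc <- sample(DNA_BASES, L, replace = TRUE)
  consensus <- matrix(rep(anc, each = S), nrow = S)
  unique_truth <- list(); shared_truth <- list()
  for (i in seq_len(S)) {
    ps <- planted[[i]]
    if (!length(ps)) next
    upos <- ps[seq_len(u)]
    spos <- if (s_sites > 0L) ps[u + seq_len(s_sites)] else integer()
    for (p in upos) {
      x <- sample(setdiff(DNA_BASES, anc[p]), 1L)
      consensus[i, p] <- x
      unique_truth[[length(unique_truth) + 1L]] <-
        data.frame(species = species[i], position = p, state = x,
                   stringsAsFactors = FALSE)
    }
    for (p in spos) {
      x <- sample(setdiff(DNA_BASES, anc[p]), 1L)
      n_sh <- sample(seq_len(cfg$max_sharers), 1L)
      # a species observed only from truncation_start onward cannot be seen
      # sharing a state at earlier positions
      candidates <- setdiff(seq_len(S), i)
      if (do_trunc && p < cfg$truncation_start)
        candidates <- setdiff(candidates, trunc_sp)
      sharers <- .sample_from(candidates, min(n_sh, length(candidates)))
      consensus[i, p] <- x
      consensus[sharers, p] <- x
      shared_truth[[length(shared_truth) + 1L]] <-
        data.frame(species = species[i], position = p, state = x,
                   sharers = paste(sort(species[sharers]), collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }

  # --- branch mutations: exact counts, disjoint sites ---------------------
  b <- stats::runif(S, cfg$divergence[1] / 2, cfg$divergence[2] / 2)
  k <- pmax(0L, round(b * L) - per_sp_planted)
  bg_pool <- setdiff(seq_len(L), all_planted)
  if (sum(k) > length(bg_pool))
    stop("infeasible config: requested divergences need ", sum(k),
         " private sites but only ", length(bg_pool), " are available; ",
         "lower the divergence range or species count")
  alloc <- .sample_from(bg_pool, sum(k))
  branch_sites <- split(alloc, rep(seq_len(S), times = k))
  for (i in seq_len(S)) {
    bs <- branch_sites[[as.character(i)]]
    if (length(bs)) consensus[i, bs] <- .mutate_base(consensus[i, bs])
  }

  # --- individuals: exact per-individual mutation counts ------------------
  mutable <- setdiff(seq_len(L), all_planted)
  m_intra <- round(cfg$intra_rate * length(mutable))
  ids <- character(0); sp_of <- character(0)
  seqs <- matrix("", nrow = sum(n_ind), ncol = L)
  r <- 0L
  for (i in seq_len(S)) {
    for (j in seq_len(n_ind[i])) {
      r <- r + 1L
      sq <- consensus[i, ]
      if (m_intra > 0L) {
        mpos <- .sample_from(mutable, m_intra)
        sq[mpos] <- .mutate_base(sq[mpos])
      }
      seqs[r, ] <- sq
      ids <- c(ids, sprintf("%s_ind%03d", species[i], j))
      sp_of <- c(sp_of, species[i])
    }
  }

  # --- ambiguities (never at planted sites) -------------------------------
  if (cfg$ambiguity_rate > 0) {
    two_fold <- c("M", "R", "W", "S", "Y", "K")
    for (r in seq_len(nrow(seqs))) {
      hits <- mutable[stats::runif(length(mutable)) < cfg$ambiguity_rate]
      for (p in hits) {
        base <- seqs[r, p]
        codes <- two_fold[vapply(two_fold,
                                 function(cd) base %in% IUPAC_EXPAND[[cd]],
                                 logical(1))]
        seqs[r, p] <- .sample_from(codes, 1L)
      }
    }
  }

  # --- truncation (whole designated species + optional extra records) -----
  truncated_records <- integer()
  if (do_trunc) truncated_records <- which(sp_of == species[trunc_sp])
  if (cfg$truncated_fraction > 0) {
    extra <- which(stats::runif(nrow(seqs)) < cfg$truncated_fraction)
    truncated_records <- union(truncated_records, extra)
  }
  if (length(truncated_records) && cfg$truncation_start > 1L)
    seqs[truncated_records, seq_len(cfg$truncation_start - 1L)] <- "N"

  aln <- barcode_alignment(seqs, id = ids, species = sp_of, offset = 1L)

  # --- expected pairwise p-distances (consensus + intra correction) -------
  exp_pair <- matrix(0, S, S, dimnames = list(species, species))
  trunc_cols <- if (do_trunc) seq(cfg$truncation_start, L) else seq_len(L)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    if (j <= i) next
    W <- if (do_trunc && (i == trunc_sp || j == trunc_sp)) trunc_cols else seq_len(L)
    mutW <- intersect(mutable, W)
    d_full <- sum(consensus[i, W] != consensus[j, W])
    d_bg <- sum(consensus[i, mutW] != consensus[j, mutW])
    m_eff <- m_intra * length(mutW) / length(mutable)
    e_mism <- d_full + 2 * m_eff * (1 - (4 / 3) * d_bg / length(mutW))
    exp_pair[i, j] <- exp_pair[j, i] <- e_mism / length(W)
  }

  truth <- structure(list(
    generator_version = as.character(utils::packageVersion("barcodiag")),
    seed = seed,
    species = species,
    n_individuals = stats::setNames(as.integer(n_ind), species),
    planted_unique = if (length(unique_truth)) do.call(rbind, unique_truth) else
      data.frame(species = character(), position = integer(),
                 state = character(), stringsAsFactors = FALSE),
    planted_shared = if (length(shared_truth)) do.call(rbind, shared_truth) else
      data.frame(species = character(), position = integer(),
                 state = character(), sharers = character(),
                 stringsAsFactors = FALSE),
    branch_divergence = stats::setNames(b, species),
    branch_site_count = stats::setNames(as.integer(k), species),
    m_intra = as.integer(m_intra),
    n_mutable = length(mutable),
    expected_pairwise = exp_pair,
    truncated_species = if (do_trunc) species[trunc_sp] else NA_character_,
    truncation_start = if (do_trunc) cfg$truncation_start else NA_integer_),
    class = "synthetic_truth")
  list(alignment = aln, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d species, seed %d, %d planted unique + %d shared sites\n",
              length(x$species), x$seed, nrow(x$planted_unique),
              nrow(x$planted_shared)))
  invisible(x)
}

#' Serialize / restore planted simulation truth
#'
#' Lossless JSON round trip of a `synthetic_truth` object, including seed
#' and generator version; empty planted sets serialize to explicit empty
#' lists.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
truth_report <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  payload <- unclass(truth)
  payload$expected_pairwise <- as.data.frame(payload$expected_pairwise)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "columns")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname truth_report
#' @export
read_truth <- function(path) {
  p <- jsonlite::fromJSON(path)
  p$planted_unique <- as.data.frame(p$planted_unique,
                                    stringsAsFactors = FALSE)
  p$planted_shared <- as.data.frame(p$planted_shared,
                                    stringsAsFactors = FALSE)
  p$expected_pairwise[["_row"]] <- NULL
  ep <- as.matrix(as.data.frame(p$expected_pairwise))
  dimnames(ep) <- list(p$species, p$species)
  p$expected_pairwise <- ep
  p$branch_divergence <- stats::setNames(unlist(p$branch_divergence), p$species)
  p$branch_site_count <- stats::setNames(as.integer(unlist(p$branch_site_count)),
                                         p$species)
  p$n_individuals <- stats::setNames(as.integer(unlist(p$n_individuals)),
                                     p$species)
  structure(p, class = "synthetic_truth")
}
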