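#' Diagnostic character configuration
#'
#' @param k Maximum number of non-focal species allowed to share a partially
#'   diagnostic state (default 2, the conventional cap for printed
#'   diagnoses; `k = 0` degenerates to unique characters only).
#' @param require_focal_fixed If `TRUE` (default) a position is listed only
#'   when every observed focal individual carries the same unambiguous
#'   state; focal ambiguity codes disqualify the position (printed diagnoses
#'   are single-state).
#' @param rarely_max Sharing fraction at or below which a sharer is
#'   qualified `"rarely"` (default 0.1; a single sharing individual in a
#'   species with >= `rarely_n_min` observed also counts).
#' @param rarely_n_min See `rarely_max` (default 10).
#' @param most_min Sharing fraction at or above which (but below 1) a sharer
#'   is `"most"` (default 0.5); fractions strictly between the rarely band
#'   and `most_min` are `"some"`, and exactly 1 is `"all"` (rendered as a
#'   plain "except").
#' @details The verbal qualifiers of published diagnoses ("except some",
#'   "except most", "rarely also in") have no fixed numeric definition;
#'   these bands quantify them explicitly and remain configurable. The
#'   rendered output always carries the exact fraction in TSV form.
#' @return A list of class `diag_config`.
#' @export
diag_config <- function(k = 2L, require_focal_fixed = TRUE,
                        rarely_max = 0.1, rarely_n_min = 10L, most_min = 0.5) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a non-negative integer")
  stopifnot(rarely_max > 0, rarely_max < most_min, most_min <= 1)
  structure(list(k = k, require_focal_fixed = isTRUE(require_focal_fixed),
                 rarely_max = rarely_max, rarely_n_min = as.integer(rarely_n_min),
                 most_min = most_min),
            class = "diag_config")
}

# Qualifier band for a sharing fraction f = carriers/observed.
.qualifier <- function(f, carriers, observed, cfg) {
  if (f >= 1) "all"
  else if (f <= cfg$rarely_max ||
           (carriers == 1L && observed >= cfg$rarely_n_min)) "rarely"
  else if (f < cfg$most_min) "some"
  else "most"
}

# Columns (alignment-local indices) at which the focal species is "fixed"
# for one state, together with that state. With require_focal_fixed, all
# observed focal individuals must carry the same unambiguous base. Without
# it, the state must be carried (ambiguity-compatible) by every observed
# focal individual and observed unambiguously at least once. Columns with
# no observed focal individual are never diagnostic.
.focal_states <- function(profile, focal, cfg) {
  bc <- profile$base_counts[[focal]]
  at <- profile$amb_total[[focal]]
  obs <- profile$n_records[[focal]] - profile$missing[[focal]]
  L <- length(obs)
  state <- rep(NA_character_, L)
  if (cfg$require_focal_fixed) {
    for (b in DNA_BASES) {
      hit <- obs > 0L & at == 0L & bc[b, ] == obs
      state[hit] <- b
    }
  } else {
    carrier <- bc + profile$amb_carrier[[focal]]
    for (b in DNA_BASES) {
      hit <- obs > 0L & carrier[b, ] == obs & bc[b, ] > 0L
      state[hit & is.na(state)] <- b
    }
  }
  state
}

# Carrier counts of base b across all non-focal species: returns a
# species x L matrix of carriers and of observed counts.
.other_counts <- function(profile, focal) {
  others <- setdiff(profile$species, focal)
  list(others = others,
       carriers = function(b) do.call(rbind, lapply(others, function(s)
         profile$base_counts[[s]][b, ] + profile$amb_carrier[[s]][b, ])),
       observed = do.call(rbind, lapply(others, function(s)
         profile$n_records[[s]] - profile$missing[[s]])))
}

#' Find unique diagnostic substitutions for a species
#'
#' A position is a unique diagnostic when the focal species is fixed for an
#' unambiguous state there and no observed individual of any other species
#' carries that state (an ambiguity code whose expansion includes the state
#' counts as carrying it). Missing data in other species does not veto
#' uniqueness: uniqueness is among observed states.
#'
#' @param profile A [site_state_profile()].
#' @param focal Focal species label.
#' @param cfg A [diag_config()].
#' @return Data frame of class `diagnostic_characters` with one row per
#'   character: `position` (reference coordinate), `state`, `kind`
#'   (`"unique"`), `focal_observed`, plus empty sharer columns; sorted by
#'   position.
#' @export
find_unique_diagnostics <- function(profile, focal, cfg = diag_config()) {
  .check_focal(profile, focal)
  state <- .focal_states(profile, focal, cfg)
  oc <- .other_counts(profile, focal)
  rows <- list()
  for (b in DNA_BASES) {
    cols <- which(state == b)
    if (!length(cols)) next
    carr <- oc$carriers(b)
    shared_by <- colSums(carr[, cols, drop = FALSE] > 0L)
    uniq_cols <- cols[shared_by == 0L]
    for (cl in uniq_cols) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = profile$positions[cl], state = b, kind = "unique",
        sharer = NA_character_, qualifier = NA_character_,
        fraction = NA_real_, carriers = NA_integer_, observed = NA_integer_,
        focal_observed = .observed_at(profile, focal, cl),
        stringsAsFactors = FALSE)
    }
  }
  .as_characters(rows, focal)
}

#' Find partially shared diagnostic substitutions
#'
#' Positions where the focal species is fixed for a state that occurs in at
#' least 1 and at most `k` other species (a species shares when at least one
#' observed individual carries the state or an ambiguity covering it). Each
#' sharer is annotated with its sharing fraction and verbal qualifier.
#' Unique positions are not repeated here.
#'
#' @inheritParams find_unique_diagnostics
#' @return Data frame of class `diagnostic_characters`, one row per
#'   (position, sharer): columns as in [find_unique_diagnostics()] with
#'   `kind = "shared"` and sharer fields filled; sorted by position, sharers
#'   alphabetically within a position.
#' @export
find_shared_diagnostics <- function(profile, focal, cfg = diag_config()) {
  .check_focal(profile, focal)
  if (cfg$k == 0L) return(.as_characters(list(), focal))
  state <- .focal_states(profile, focal, cfg)
  oc <- .other_counts(profile, focal)
  rows <- list()
  for (b in DNA_BASES) {
    cols <- which(state == b)
    if (!length(cols)) next
    carr <- oc$carriers(b)
    n_sharing <- colSums(carr[, cols, drop = FALSE] > 0L)
    keep <- cols[n_sharing >= 1L & n_sharing <= cfg$k]
    for (cl in keep) {
      sharers <- oc$others[carr[, cl] > 0L]
      for (s in sort(sharers)) {
        cr <- .carriers_at(profile, s, b, cl)
        ob <- .observed_at(profile, s, cl)
        f <- cr / ob
        rows[[length(rows) + 1L]] <- data.frame(
          position = profile$positions[cl], state = b, kind = "shared",
          sharer = s, qualifier = .qualifier(f, cr, ob, cfg),
          fraction = f, carriers = cr, observed = ob,
          focal_observed = .observed_at(profile, focal, cl),
          stringsAsFactors = FALSE)
      }
    }
  }
  .as_characters(rows, focal)
}

.check_focal <- function(profile, focal) {
  stopifnot(inherits(profile, "state_profile"))
  if (!focal %in% profile$species)
    stop("unknown focal species '", focal, "'")
}

.as_characters <- function(rows, focal) {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), state = character(), kind = character(),
               sharer = character(), qualifier = character(),
               fraction = numeric(), carriers = integer(), observed = integer(),
               focal_observed = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$state, out$sharer,
                   method = "radix", na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("diagnostic_characters", "data.frame"),
            focal = focal)
}

#' Verify that a character combination excludes all other species
#'
#' Individual-level check of the "unique combination" claim: the listed
#' characters verify when every non-focal individual that has observed data
#' at at least one listed position conflicts with the focal state at some
#' listed position. An ambiguity code overlapping the focal state is not a
#' conflict; absence of data is never evidence of difference, so
#' individuals (and species) with zero overlap at the listed positions are
#' reported as unverifiable rather than counted as failures.
#'
#' @param profile A [site_state_profile()].
#' @param focal Focal species label.
#' @param characters A `diagnostic_characters` data frame (or any data frame
#'   with `position` and `state` columns); must be non-empty.
#' @return List with `verified` (logical), `unverifiable` (data frame
#'   `record_id`, `species`, `reason`), `witnesses` (data frame `species`,
#'   `position`: for each non-focal species, the first listed position that
#'   excludes every one of its overlapping individuals, or `NA` if no single
#'   position does — verification itself is per-individual), and
#'   `failing_records` (ids of overlapping individuals not excluded).
#' @export
verify_combination <- function(profile, focal, characters) {
  .check_focal(profile, focal)
  if (NROW(characters) == 0L)
    stop("character list is empty; nothing to verify")
  chars <- unique(data.frame(position = characters$position,
                             state = characters$state,
                             stringsAsFactors = FALSE))
  chars <- chars[order(chars$position), , drop = FALSE]
  aln <- profile$aln
  cols <- chars$position - aln$offset + 1L
  if (any(cols < 1L | cols > n_columns(aln)))
    stop("character positions outside the alignment")
  sub <- aln$seq[, cols, drop = FALSE]
  other_idx <- which(aln$species != focal)
  unver <- list(); fails <- character()
  conflict <- matrix(FALSE, length(other_idx), length(cols))
  for (j in seq_along(cols)) {
    x <- sub[other_idx, j]
    observed <- !.is_missing(x)
    conflict[, j] <- observed & !.carries(x, chars$state[j])
  }
  overlap <- matrix(!.is_missing(sub[other_idx, , drop = FALSE]),
                    nrow = length(other_idx))
  has_overlap <- rowSums(overlap) > 0L
  excluded <- rowSums(conflict) > 0L
  for (i in seq_along(other_idx)) {
    r <- other_idx[i]
    if (!has_overlap[i]) {
      unver[[length(unver) + 1L]] <- data.frame(
        record_id = aln$id[r], species = aln$species[r],
        reason = "no overlap at diagnostic positions",
        stringsAsFactors = FALSE)
    } else if (!excluded[i]) {
      fails <- c(fails, aln$id[r])
    }
  }
  other_species <- sort(unique(aln$species[other_idx]))
  witnesses <- do.call(rbind, lapply(other_species, function(s) {
    rows <- which(aln$species[other_idx] == s & has_overlap)
    pos <- NA_integer_
    if (length(rows)) {
      for (j in seq_along(cols)) {
        relevant <- rows[overlap[rows, j]]
        if (length(relevant) == length(rows) && all(conflict[relevant, j])) {
          pos <- chars$position[j]; break
        }
      }
    }
    data.frame(species = s, position = pos, stringsAsFactors = FALSE)
  }))
  list(verified = length(fails) == 0L && any(has_overlap),
       unverifiable = if (length(unver)) do.call(rbind, unver) else
         data.frame(record_id = character(), species = character(),
                    reason = character(), stringsAsFactors = FALSE),
       witnesses = witnesses,
       failing_records = fails)
}

#' Full DNA diagnosis of one species
#'
#' Pipeline of [site_state_profile()], [find_unique_diagnostics()],
#' [find_shared_diagnostics()] and [verify_combination()] (the latter over
#' the union of unique and shared characters). Deterministic.
#'
#' @param aln A `barcode_alignment`.
#' @param focal Focal species label.
#' @param cfg A [diag_config()].
#' @param profile Optionally a precomputed [site_state_profile()] of `aln`.
#' @return Object of class `species_diagnosis`: list with `species`,
#'   `unique`, `shared` (both `diagnostic_characters`),
#'   `combination_verified`, `unverifiable`, `witnesses`, `failing_records`,
#'   `n_focal`, `preliminary` (`TRUE` when the species has a single record).
#' @export
diagnose_species <- function(aln, focal, cfg = diag_config(), profile = NULL) {
  if (is.null(profile)) profile <- site_state_profile(aln)
  .check_focal(profile, focal)
  uniq <- find_unique_diagnostics(profile, focal, cfg)
  shared <- find_shared_diagnostics(profile, focal, cfg)
  all_chars <- rbind(as.data.frame(uniq), as.data.frame(shared))
  if (nrow(all_chars)) {
    ver <- verify_combination(profile, focal, all_chars)
  } else {
    ver <- list(verified = FALSE,
                unverifiable = data.frame(record_id = character(),
                                          species = character(),
                                          reason = character(),
                                          stringsAsFactors = FALSE),
                witnesses = data.frame(species = character(),
                                       position = integer(),
                                       stringsAsFactors = FALSE),
                failing_records = character())
  }
  structure(list(species = focal, unique = uniq, shared = shared,
                 combination_verified = ver$verified,
                 unverifiable = ver$unverifiable,
                 witnesses = ver$witnesses,
                 failing_records = ver$failing_records,
                 n_focal = unname(profile$n_records[[focal]]),
                 preliminary = profile$n_records[[focal]] == 1L),
            class = "species_diagnosis")
}

#' @export
print.species_diagnosis <- function(x, ...) {
  cat(render_diagnosis(x, style = "paper"), sep = "\n")
  invisible(x)
}
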