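#' Per-species, per-position state profile
#'
#' Precomputes, for every reference position and species, the count of each
#' observed unambiguous base, the count of individuals carrying each base
#' through an ambiguity code (e.g. `R` carries both `A` and `G`), the total
#' ambiguous count, and the missing count. Totals are conserved: for every
#' (position, species), base counts + ambiguous count + missing count equal
#' the species' record count.
#'
#' @param aln A `barcode_alignment`.
#' @return An object of class `state_profile`: a list with `species`,
#'   `n_records` (named), `base_counts` (per species, 4 x L matrix of
#'   unambiguous counts), `amb_carrier` (per species, 4 x L count of
#'   ambiguous carriers per base), `amb_total` and `missing` (per species,
#'   length-L vectors), `positions` (reference coordinates), and `aln`
#'   (the source alignment, retained for individual-level verification).
#' @seealso [find_unique_diagnostics()], [verify_combination()]
#' @export
site_state_profile <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  L <- n_columns(aln)
  idx <- species_index(aln)
  species <- names(idx)
  base_counts <- amb_carrier <- vector("list", length(species))
  amb_total <- missing <- vector("list", length(species))
  names(base_counts) <- names(amb_carrier) <- species
  names(amb_total) <- names(missing) <- species
  for (sp in species) {
    sub <- aln$seq[idx[[sp]], , drop = FALSE]
    bc <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
    ac <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
    for (b in DNA_BASES) bc[b, ] <- colSums(sub == b)
    at <- integer(L)
    for (code in AMBIGUITY_CODES) {
      hits <- colSums(sub == code)
      if (any(hits > 0L)) {
        at <- at + hits
        for (b in IUPAC_EXPAND[[code]]) ac[b, ] <- ac[b, ] + hits
      }
    }
    base_counts[[sp]] <- bc
    amb_carrier[[sp]] <- ac
    amb_total[[sp]] <- at
    missing[[sp]] <- nrow(sub) - colSums(bc) - at
  }
  structure(list(species = species,
                 n_records = vapply(idx, length, integer(1)),
                 base_counts = base_counts, amb_carrier = amb_carrier,
                 amb_total = amb_total, missing = missing,
                 positions = seq_len(L) + aln$offset - 1L,
                 aln = aln),
            class = "state_profile")
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("state_profile: %d species, positions %d-%d\n",
              length(x$species), x$positions[1], x$positions[length(x$positions)]))
  invisible(x)
}

# Number of individuals of `sp` carrying base `b` at column `col`
# (unambiguous + compatible ambiguity codes).
.carriers_at <- function(profile, sp, b, col) {
  profile$base_counts[[sp]][b, col] + profile$amb_carrier[[sp]][b, col]
}

# Number of observed (non-missing) individuals of `sp` at column `col`.
.observed_at <- function(profile, sp, col) {
  profile$n_records[[sp]] - profile$missing[[sp]][col]
}
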