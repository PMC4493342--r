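# Brute-force oracles and fixture builders. These re-derive every quantity
# by direct enumeration over individuals, positions and states, sharing no
# code with the implementation under test.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"))
MISSING <- c("-", "N", "?")

# build a barcode_alignment from strings
toy_aln <- function(seqs, species, id = NULL, offset = 1L) {
  if (is.null(id)) id <- sprintf("r%02d", seq_along(seqs))
  barcode_alignment(seqs, id = id, species = species, offset = offset)
}

# random species-structured alignment with missing data and ambiguities
random_alignment <- function(seed, n_species = NULL, max_ind = 8L,
                             n_pos = NULL, p_missing = 0.05, p_ambig = 0.03) {
  set.seed(seed)
  if (is.null(n_species)) n_species <- sample(2:6, 1)
  if (is.null(n_pos)) n_pos <- sample(20:60, 1)
  species <- sprintf("sp%02d", seq_len(n_species))
  rows <- list(); sp_of <- character()
  for (s in species) {
    n <- sample(seq_len(max_ind), 1)
    base <- sample(c("A", "C", "G", "T"), n_pos, replace = TRUE)
    for (k in seq_len(n)) {
      sq <- base
      mut <- runif(n_pos) < 0.1
      sq[mut] <- sapply(sq[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1))
      amb <- runif(n_pos) < p_ambig
      sq[amb] <- sample(c("M", "R", "W", "S", "Y", "K"), sum(amb), replace = TRUE)
      mis <- runif(n_pos) < p_missing
      sq[mis] <- sample(MISSING, sum(mis), replace = TRUE)
      rows[[length(rows) + 1L]] <- paste(sq, collapse = "")
      sp_of <- c(sp_of, s)
    }
  }
  toy_aln(unlist(rows), sp_of)
}

bf_carries <- function(sym, b) !(sym %in% MISSING) && b %in% IUPAC[[sym]]

# enumerate unique diagnostics by looping over every position and state
bf_unique <- function(aln, focal) {
  rows <- which(aln$species == focal)
  other <- which(aln$species != focal)
  out <- data.frame(position = integer(), state = character(),
                    stringsAsFactors = FALSE)
  for (col in seq_len(ncol(aln$seq))) {
    obs <- aln$seq[rows, col]
    obs <- obs[!(obs %in% MISSING)]
    if (!length(obs)) next
    if (length(unique(obs)) != 1L) next
    s <- unique(obs)
    if (!(s %in% c("A", "C", "G", "T"))) next   # focal ambiguity disqualifies
    shared <- FALSE
    for (r in other) if (bf_carries(aln$seq[r, col], s)) { shared <- TRUE; break }
    if (!shared)
      out <- rbind(out, data.frame(position = col + aln$offset - 1L, state = s,
                                   stringsAsFactors = FALSE))
  }
  out
}

# enumerate shared diagnostics: focal fixed state present in 1..k other species
bf_shared <- function(aln, focal, k = 2L) {
  other_species <- setdiff(unique(aln$species), focal)
  rows <- which(aln$species == focal)
  out <- data.frame(position = integer(), state = character(),
                    sharer = character(), fraction = numeric(),
                    stringsAsFactors = FALSE)
  if (k == 0L) return(out)
  for (col in seq_len(ncol(aln$seq))) {
    obs <- aln$seq[rows, col]
    obs <- obs[!(obs %in% MISSING)]
    if (!length(obs) || length(unique(obs)) != 1L) next
    s <- unique(obs)
    if (!(s %in% c("A", "C", "G", "T"))) next
    sharers <- character(); fracs <- numeric()
    for (osp in other_species) {
      orow <- which(aln$species == osp)
      syms <- aln$seq[orow, col]
      seen <- syms[!(syms %in% MISSING)]
      if (!length(seen)) next
      carry <- sum(vapply(seen, function(x) bf_carries(x, s), logical(1)))
      if (carry > 0) { sharers <- c(sharers, osp); fracs <- c(fracs, carry / length(seen)) }
    }
    if (length(sharers) >= 1L && length(sharers) <= k) {
      ord <- order(sharers)
      out <- rbind(out, data.frame(position = col + aln$offset - 1L, state = s,
                                   sharer = sharers[ord], fraction = fracs[ord],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# brute-force combination verification at the individual level
bf_verify <- function(aln, focal, positions, states) {
  cols <- positions - aln$offset + 1L
  other <- which(aln$species != focal)
  unver <- character(); ok <- TRUE; any_overlap <- FALSE
  for (r in other) {
    syms <- aln$seq[r, cols]
    observed <- !(syms %in% MISSING)
    if (!any(observed)) { unver <- c(unver, aln$id[r]); next }
    any_overlap <- TRUE
    conflict <- FALSE
    for (j in which(observed))
      if (!bf_carries(syms[j], states[j])) { conflict <- TRUE; break }
    if (!conflict) ok <- FALSE
  }
  list(verified = ok && any_overlap, unverifiable_ids = unver)
}

# connected components by repeated expansion (single linkage at threshold)
bf_components <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (!is.na(d[i, j]) && d[i, j] <= threshold && comp[j] != comp[i]) {
        tgt <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# membership vectors describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
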