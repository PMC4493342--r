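#' IUPAC nucleotide ambiguity expansions
#'
#' Expansion sets for the IUPAC DNA alphabet used throughout the package.
#' Gap (`-`) and the fully unknown symbols (`N`, `?`) are treated as missing
#' data, not as ambiguity codes: they carry no state information at a site.
#'
#' @format A named list mapping each symbol to the character vector of
#'   unambiguous bases it denotes.
#' @keywords internal
IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")
AMBIGUITY_CODES <- setdiff(names(IUPAC_EXPAND), DNA_BASES)
MISSING_SYMBOLS <- c("-", "N", "?")
VALID_SYMBOLS <- c(names(IUPAC_EXPAND), MISSING_SYMBOLS)

# TRUE where the symbol denotes an observed unambiguous base
.is_base <- function(x) x %in% DNA_BASES

# TRUE where the symbol is an ambiguity code (2- or 3-fold)
.is_ambig <- function(x) x %in% AMBIGUITY_CODES

# TRUE where the symbol carries no information ('-', 'N', '?')
.is_missing <- function(x) x %in% MISSING_SYMBOLS

# TRUE where symbol `x` is compatible with base `b`: unambiguous equal, or an
# ambiguity code whose expansion contains `b`. Missing symbols are never
# carriers.
.carries <- function(x, b) {
  vapply(x, function(s) {
    if (s %in% MISSING_SYMBOLS) return(FALSE)
    b %in% IUPAC_EXPAND[[s]]
  }, logical(1), USE.NAMES = FALSE)
}
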