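#' Render a species diagnosis
#'
#' `style = "paper"` emits the compact printed form: unique substitutions as
#' `STATE (POS)` and partially shared ones as
#' `STATE (POS, except [qualifier ]species, ...)`, where the qualifier is
#' empty for sharers carrying the state in all observed individuals and one
#' of `most`, `some`, `rarely` otherwise; items are sorted by position and
#' sharers alphabetically. `style = "tsv"` emits one row per character (and
#' per sharer) with all fields. The paper style is parseable back to the
#' character list via [parse_diagnosis()], and render -> parse -> render is
#' a fixed point.
#'
#' @param d A `species_diagnosis`.
#' @param style `"paper"` or `"tsv"`.
#' @return Character vector of output lines.
#' @export
render_diagnosis <- function(d, style = c("paper", "tsv")) {
  style <- match.arg(style)
  if (style == "tsv") return(.render_tsv(d))
  lines <- c(sprintf("## %s", d$species),
             sprintf("Barcodes examined: %d%s", d$n_focal,
                     if (d$preliminary) " (single record; diagnosis preliminary)" else ""))
  if (nrow(d$unique) == 0L && nrow(d$shared) == 0L) {
    lines <- c(lines, "No diagnostic sites found.")
  } else {
    if (nrow(d$unique) > 0L) {
      items <- sprintf("%s (%d)", d$unique$state, d$unique$position)
      lines <- c(lines, paste0("Unique substitutions: ",
                               paste(items, collapse = ", "), "."))
    }
    if (nrow(d$shared) > 0L) {
      sh <- as.data.frame(d$shared)
      keys <- unique(sh[, c("position", "state")])
      items <- vapply(seq_len(nrow(keys)), function(i) {
        rows <- sh[sh$position == keys$position[i] & sh$state == keys$state[i], ]
        rows <- rows[order(rows$sharer), ]
        tags <- ifelse(rows$qualifier == "all", rows$sharer,
                       paste(rows$qualifier, rows$sharer))
        sprintf("%s (%d, except %s)", keys$state[i], keys$position[i],
                paste(tags, collapse = ", "))
      }, character(1))
      lines <- c(lines, paste0("Partially shared substitutions: ",
                               paste(items, collapse = ", "), "."))
    }
  }
  lines <- c(lines, sprintf("Combination verified: %s.",
                            if (isTRUE(d$combination_verified)) "yes" else "no"))
  if (nrow(d$unverifiable) > 0L) {
    sp <- sort(unique(d$unverifiable$species))
    lines <- c(lines, paste0("Unverifiable (no overlap at diagnostic positions): ",
                             paste(sp, collapse = ", "), "."))
  }
  lines
}

.render_tsv <- function(d) {
  df <- rbind(as.data.frame(d$unique), as.data.frame(d$shared))
  header <- paste(c("species", "position", "state", "kind", "sharer",
                    "qualifier", "fraction", "carriers", "observed",
                    "focal_observed"), collapse = "\t")
  if (nrow(df) == 0L) return(header)
  body <- vapply(seq_len(nrow(df)), function(i) paste(c(
    d$species, df$position[i], df$state[i], df$kind[i],
    ifelse(is.na(df$sharer[i]), "", df$sharer[i]),
    ifelse(is.na(df$qualifier[i]), "", df$qualifier[i]),
    ifelse(is.na(df$fraction[i]), "", format(df$fraction[i])),
    ifelse(is.na(df$carriers[i]), "", df$carriers[i]),
    ifelse(is.na(df$observed[i]), "", df$observed[i]),
    df$focal_observed[i]), collapse = "\t"), character(1))
  c(header, body)
}

#' Parse a paper-style rendered diagnosis
#'
#' Inverse of [render_diagnosis()] for `style = "paper"`: recovers the
#' species, the unique and shared character lists (positions, states,
#' sharers and qualifiers) and the verification flag. Count and fraction
#' fields that the compact style does not print come back as `NA`.
#'
#' @param lines Character vector as produced by `render_diagnosis(style = "paper")`.
#' @return A list shaped like a `species_diagnosis` (fields `species`,
#'   `unique`, `shared`, `combination_verified`).
#' @export
parse_diagnosis <- function(lines) {
  sp_line <- grep("^## ", lines, value = TRUE)
  if (!length(sp_line)) stop("not a rendered diagnosis: no species header")
  species <- sub("^## ", "", sp_line[1])
  n_line <- grep("^Barcodes examined: ", lines, value = TRUE)
  n_focal <- if (length(n_line))
    as.integer(sub("^Barcodes examined: (\\d+).*$", "\\1", n_line[1])) else NA_integer_
  preliminary <- length(n_line) > 0 && grepl("preliminary", n_line[1])
  pull_items <- function(prefix) {
    ln <- grep(prefix, lines, value = TRUE)
    if (!length(ln)) return(character())
    body <- sub("\\.$", "", sub(prefix, "", ln[1]))
    m <- gregexpr("[ACGT] \\([^)]*\\)", body)[[1]]
    if (m[1] == -1) return(character())
    regmatches(body, gregexpr("[ACGT] \\([^)]*\\)", body))[[1]]
  }
  uniq_items <- pull_items("^Unique substitutions: ")
  shared_items <- pull_items("^Partially shared substitutions: ")
  uniq <- lapply(uniq_items, function(it) {
    data.frame(position = as.integer(sub("^[ACGT] \\((\\d+)\\)$", "\\1", it)),
               state = substr(it, 1, 1), kind = "unique",
               sharer = NA_character_, qualifier = NA_character_,
               fraction = NA_real_, carriers = NA_integer_,
               observed = NA_integer_, focal_observed = NA_integer_,
               stringsAsFactors = FALSE)
  })
  shared <- lapply(shared_items, function(it) {
    state <- substr(it, 1, 1)
    inner <- sub("^[ACGT] \\((.*)\\)$", "\\1", it)
    pos <- as.integer(sub("^(\\d+), except .*$", "\\1", inner))
    tags <- strsplit(sub("^\\d+, except ", "", inner), ", ", fixed = TRUE)[[1]]
    do.call(rbind, lapply(tags, function(tg) {
      parts <- strsplit(tg, " ", fixed = TRUE)[[1]]
      if (length(parts) == 2L && parts[1] %in% c("most", "some", "rarely")) {
        qual <- parts[1]; shr <- parts[2]
      } else {
        qual <- "all"; shr <- tg
      }
      data.frame(position = pos, state = state, kind = "shared",
                 sharer = shr, qualifier = qual, fraction = NA_real_,
                 carriers = NA_integer_, observed = NA_integer_,
                 focal_observed = NA_integer_, stringsAsFactors = FALSE)
    }))
  })
  verified <- any(grepl("^Combination verified: yes\\.$", lines))
  unver_line <- grep("^Unverifiable", lines, value = TRUE)
  unver_species <- if (length(unver_line)) {
    strsplit(sub("\\.$", "",
                 sub("^Unverifiable[^:]*: ", "", unver_line[1])), ", ")[[1]]
  } else character()
  structure(list(
    species = species,
    unique = .as_characters(uniq, species),
    shared = .as_characters(shared, species),
    combination_verified = verified,
    unverifiable = if (length(unver_species)) {
      data.frame(record_id = NA_character_, species = unver_species,
                 reason = "no overlap at diagnostic positions",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(record_id = character(), species = character(),
                 reason = character(), stringsAsFactors = FALSE)
    },
    witnesses = NULL, failing_records = NULL,
    n_focal = n_focal, preliminary = preliminary),
    class = "species_diagnosis")
}

#' Write diagnoses for all species
#'
#' @param diagnoses List of `species_diagnosis` objects.
#' @param path_md,path_tsv Output paths (markdown, one section per species;
#'   TSV, one row per character/sharer). Either may be `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_diagnoses <- function(diagnoses, path_md = NULL, path_tsv = NULL) {
  if (!is.null(path_md)) {
    md <- unlist(lapply(diagnoses, function(d) c(render_diagnosis(d, "paper"), "")))
    writeLines(md, path_md)
  }
  if (!is.null(path_tsv)) {
    tsvs <- lapply(diagnoses, .render_tsv)
    header <- tsvs[[1]][1]
    body <- unlist(lapply(tsvs, function(x) x[-1]))
    writeLines(c(header, body), path_tsv)
  }
  invisible(c(path_md, path_tsv))
}
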