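#' Built-in frequency lexicon
#'
#' The lexicon maps canonical administration-frequency labels to the
#' equivalent number of administrations per 24-hour day. Rates below 1 are
#' legitimate ("every other day" is 0.5; "weekly" is 1/7). PRN ("as needed")
#' qualifiers never change the rate: for days-supply purposes an as-needed sig
#' is interpreted at its maximum allowed frequency, so "twice a day PRN" is
#' two administrations per day, exactly like "twice a day".
#'
#' EHR frequency vocabularies vary between sites, so the built-in table is a
#' seed, not a closed list: merge site-specific labels over it with
#' [frequency_lexicon()].
#'
#' @return A tibble with columns `label` (canonical lower-case label) and
#'   `rate` (administrations per day, positive real).
#' @seealso [frequency_lexicon()], [map_frequency()]
#' @export
#' @examples
#' default_frequency_lexicon()
default_frequency_lexicon <- function() {
  tibble::tibble(
    label = c(
      "daily", "once a day", "once daily", "every day", "qd",
      "every 24 hours",
      "twice a day", "twice daily", "two times a day", "bid",
      "three times a day", "three times daily", "tid",
      "four times a day", "four times daily", "qid",
      "every 3 hours", "q3h",
      "every 4 hours", "q4h",
      "every 6 hours", "q6h",
      "every 8 hours", "q8h",
      "every 12 hours", "q12h",
      "every other day", "qod",
      "nightly", "at bedtime", "qhs",
      "weekly", "once a week"
    ),
    rate = c(
      1, 1, 1, 1, 1,
      1,
      2, 2, 2, 2,
      3, 3, 3,
      4, 4, 4,
      8, 8,
      6, 6,
      4, 4,
      3, 3,
      2, 2,
      0.5, 0.5,
      1, 1, 1,
      1 / 7, 1 / 7
    )
  )
}

#' Assemble a frequency lexicon, optionally merged with site-specific labels
#'
#' Site labels (from a two-column `label,rate` CSV and/or an in-memory data
#' frame) are merged over the built-in defaults; on a label collision the
#' site-supplied rate wins. Labels are canonicalized (lower case, collapsed
#' whitespace) before merging so lookups are case- and spacing-insensitive.
#'
#' @param path Optional path to a CSV with columns `label,rate`.
#' @param extra Optional data frame with columns `label` and `rate`.
#' @param base Base lexicon to merge over (default [default_frequency_lexicon()]).
#' @return A tibble with columns `label`, `rate`; all rates positive.
#' @export
frequency_lexicon <- function(path = NULL, extra = NULL,
                              base = default_frequency_lexicon()) {
  lex <- base
  if (!is.null(path)) {
    site <- readr::read_csv(path, col_types = readr::cols(
      label = readr::col_character(), rate = readr::col_double()
    ), progress = FALSE)
    lex <- merge_lexicon(lex, site)
  }
  if (!is.null(extra)) {
    lex <- merge_lexicon(lex, tibble::as_tibble(extra))
  }
  lex$label <- canonical_label(lex$label)
  if (anyDuplicated(lex$label)) {
    lex <- lex[!duplicated(lex$label, fromLast = TRUE), ]
  }
  if (any(!is.finite(lex$rate) | lex$rate <= 0)) {
    stop("frequency lexicon rates must be positive and finite", call. = FALSE)
  }
  lex[order(lex$label), ]
}

merge_lexicon <- function(base, site) {
  stopifnot(all(c("label", "rate") %in% names(site)))
  site <- tibble::tibble(label = canonical_label(site$label),
                         rate = as.numeric(site$rate))
  base$label <- canonical_label(base$label)
  dplyr::bind_rows(base[!base$label %in% site$label, ], site)
}

# lower-case, trim, collapse internal whitespace
canonical_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# drop PRN / "as needed" qualifiers anywhere in the label
strip_prn <- function(x) {
  x <- gsub("\\bprn\\b|\\bas needed\\b|\\bpro re nata\\b", " ", x)
  canonical_label(x)
}

#' Map a frequency label to administrations per day
#'
#' Looks the label up in the lexicon after canonicalization and after
#' stripping any PRN / "as needed" qualifier: as-needed sigs are scored at the
#' maximum allowed frequency, so the qualifier never changes the rate. Labels
#' that are missing or not in the lexicon map to `NA` (the prescription
#' becomes uncomputable downstream and is counted, never guessed at); the
#' unmapped labels are returned in the `"unmapped"` attribute for logging.
#'
#' @param frequency_label Character vector of raw frequency labels.
#' @param lexicon Lexicon tibble from [frequency_lexicon()].
#' @return Numeric vector of administrations per day (`NA` where unmapped),
#'   with attribute `unmapped` holding the unique unrecognized labels.
#' @export
#' @examples
#' map_frequency(c("twice a day PRN", "every other day", "Every 4 Hours"))
map_frequency <- function(frequency_label, lexicon = default_frequency_lexicon()) {
  key <- strip_prn(canonical_label(frequency_label))
  key[is.na(frequency_label) | key == ""] <- NA_character_
  idx <- match(key, canonical_label(lexicon$label))
  out <- lexicon$rate[idx]
  unmapped <- unique(key[!is.na(key) & is.na(idx)])
  attr(out, "unmapped") <- unmapped
  out
}
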