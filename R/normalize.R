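#' Normalize linkage identifiers
#'
#' Puts names, date of birth and SSN into the canonical comparison form used
#' by the match-key cascade and the agreement score:
#' names are upper-cased, whitespace-trimmed, diacritics folded to ASCII and
#' all non-alphabetic characters removed; the SSN is reduced to digits and
#' treated as missing (empty string) unless exactly nine digits remain.
#' The transformation is idempotent.
#'
#' @param records data frame with columns `first_name`, `last_name`,
#'   `dob` (Date) and `ssn` (character); other columns pass through.
#' @return the same data frame with identifiers normalized.
#' @export
#' @examples
#' normalize_identifiers(data.frame(
#'   first_name = "  García ", last_name = "o'neil",
#'   dob = as.Date("1980-05-02"), ssn = "123-45-6789"))
normalize_identifiers <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("first_name", "last_name", "dob", "ssn") %in% names(records)))
  records$first_name <- normalize_name(records$first_name)
  records$last_name <- normalize_name(records$last_name)
  records$ssn <- normalize_ssn(records$ssn)
  records$dob <- as.Date(records$dob)
  records
}

normalize_name <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  x <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT", sub = "")
  x[is.na(x)] <- ""
  gsub("[^A-Z]", "", toupper(x))
}

normalize_ssn <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  x <- gsub("[^0-9]", "", x)
  ifelse(nchar(x) == 9L, x, "")
}

#' The eleven built-in match-key specifications
#'
#' The deterministic cascade tries these keys in order; a record pair links
#' at the first (lowest) level whose keys are defined on both sides and
#' equal. Letter indexing is 1-based inclusive; a name shorter than a
#' slice's start position yields no key at that level, and a name shorter
#' than the slice's end uses the available characters. Level 11 is printed
#' identically to level 9 in the source algorithm and is therefore
#' unreachable; it is kept as specified.
#'
#' @return a list of 11 elements; each element is a list of component
#'   descriptors `list(field =, from =, to =)` where `field` is one of
#'   `"ssn"`, `"first"`, `"last"`, `"dob"`, `"dob_day"`, `"dob_month"`,
#'   `"dob_year"` and `from`/`to` give the 1-based letter slice for name
#'   fields (`NA` means the whole name).
#' @export
match_key_specs <- function() {
  nm <- function(field, from = NA_integer_, to = NA_integer_) {
    list(field = field, from = from, to = to)
  }
  list(
    # 1: SSN alone
    list(nm("ssn")),
    # 2: first name (first 6 letters), last name, date of birth
    list(nm("first", 1L, 6L), nm("last"), nm("dob")),
    # 3: last (1), last (3-8), first (2-8), date of birth
    list(nm("last", 1L, 1L), nm("last", 3L, 8L), nm("first", 2L, 8L), nm("dob")),
    # 4: last (1), last (3-8), first (2-8), birth month, birth year
    list(nm("last", 1L, 1L), nm("last", 3L, 8L), nm("first", 2L, 8L),
         nm("dob_month"), nm("dob_year")),
    # 5: last (1), last (3-8), first (2-8), birth day, birth year
    list(nm("last", 1L, 1L), nm("last", 3L, 8L), nm("first", 2L, 8L),
         nm("dob_day"), nm("dob_year")),
    # 6: last name, first name (1-2), date of birth
    list(nm("last"), nm("first", 1L, 2L), nm("dob")),
    # 7: last (1-3), first (1-3), date of birth
    list(nm("last", 1L, 3L), nm("first", 1L, 3L), nm("dob")),
    # 8: last (1-4), first (1-4), birth year
    list(nm("last", 1L, 4L), nm("first", 1L, 4L), nm("dob_year")),
    # 9: first (1-3), last (1-3), birth month, birth year
    list(nm("first", 1L, 3L), nm("last", 1L, 3L), nm("dob_month"), nm("dob_year")),
    # 10: first (1-3), last (1-3), birth day, birth year
    list(nm("first", 1L, 3L), nm("last", 1L, 3L), nm("dob_day"), nm("dob_year")),
    # 11: as printed, identical to 9 (unreachable behind it)
    list(nm("first", 1L, 3L), nm("last", 1L, 3L), nm("dob_month"), nm("dob_year"))
  )
}

# slice a vector of normalized names; NA where the name is shorter than
# `from` (including empty names)
name_slice <- function(x, from, to) {
  n <- nchar(x)
  out <- substr(x, from, pmin(to, n))
  out[n < from] <- NA_character_
  out
}

#' Build the level-specific match key for normalized records
#'
#' @param records normalized data frame (see [normalize_identifiers()]).
#' @param level integer 1-11 selecting the key specification.
#' @return character vector of keys (components joined by `"|"`), `NA`
#'   where any required component is unavailable (missing SSN or DOB,
#'   name shorter than the slice start).
#' @export
build_match_key <- function(records, level) {
  if (!(is.numeric(level) && length(level) == 1L && !is.na(level) &&
        level %in% 1:11)) {
    stop("'level' must be a single integer between 1 and 11", call. = FALSE)
  }
  spec <- match_key_specs()[[level]]
  dob <- as.Date(records$dob)
  parts <- lapply(spec, function(cmp) {
    switch(cmp$field,
      ssn = {
        s <- records$ssn
        ifelse(is.na(s) | s == "", NA_character_, s)
      },
      first = full_or_slice(records$first_name, cmp),
      last = full_or_slice(records$last_name, cmp),
      dob = ifelse(is.na(dob), NA_character_, format(dob, "%Y-%m-%d")),
      dob_day = ifelse(is.na(dob), NA_character_, format(dob, "%d")),
      dob_month = ifelse(is.na(dob), NA_character_, format(dob, "%m")),
      dob_year = ifelse(is.na(dob), NA_character_, format(dob, "%Y"))
    )
  })
  key <- do.call(paste, c(parts, sep = "|"))
  bad <- Reduce(`|`, lapply(parts, is.na))
  key[bad] <- NA_character_
  key
}

full_or_slice <- function(x, cmp) {
  if (is.na(cmp$from)) {
    ifelse(is.na(x) | x == "", NA_character_, x)
  } else {
    name_slice(ifelse(is.na(x), "", x), cmp$from, cmp$to)
  }
}
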