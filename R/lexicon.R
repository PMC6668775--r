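# Lexicon I/O, orthographic cue extraction and DISC demi-syllable decomposition.

#' Default DISC nucleus inventory
#'
#' The set of DISC symbols treated as syllable nuclei when decomposing a
#' phonological transcription into demi-syllables. The default covers the
#' CELEX DISC monophthongs, long vowels and diphthongs; syllabic consonants
#' are deliberately excluded. Every function that inspects phonology takes a
#' `nuclei` argument, so the inventory can be edited without touching code.
#'
#' @return Character vector of single DISC symbols.
#' @export
#' @examples
#' is_vowel("8")           # TRUE: the vowel of "bear" (b8R)
#' is_vowel("b")           # FALSE
disc_nuclei <- function() {
  c(
    "I", "E", "{", "Q", "V", "U", "@", # short vowels
    "i", "#", "$", "u", "3",           # long vowels
    "1", "2", "4", "5", "6", "7", "8", "9", # diphthongs
    "e", "a", "o", "|", "A", "O", "y"  # additional CELEX vowel codes
  )
}

#' Test whether a DISC symbol is a syllable nucleus
#'
#' @param symbol Single DISC character.
#' @param nuclei Nucleus inventory, see [disc_nuclei()].
#' @return Logical.
#' @export
is_vowel <- function(symbol, nuclei = disc_nuclei()) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("`symbol` must be a single DISC character", call. = FALSE)
  }
  symbol %in% nuclei
}

#' Extract orthographic cues from a letter string
#'
#' The orthographic code of the model: each distinct letter is a unigram cue
#' (without boundary marks) and each letter bigram of the boundary-marked
#' string `#word#` is a bigram cue. For `"bear"` the cues are the letters
#' `b, e, a, r` and the bigrams `#b, be, ea, ar, r#`. Cue presence is binary,
#' so repeated letters or bigrams contribute a single cue (set semantics).
#'
#' @param orthography Non-empty lowercase letter string (`a`-`z`).
#' @return Character vector of unique cues.
#' @export
#' @examples
#' extract_cues("bear")
extract_cues <- function(orthography) {
  if (!is.character(orthography) || length(orthography) != 1L ||
      !grepl("^[a-z]+$", orthography)) {
    stop("`orthography` must be a non-empty lowercase a-z string, got: ",
         deparse(orthography), call. = FALSE)
  }
  letters1 <- unique(strsplit(orthography, "", fixed = TRUE)[[1L]])
  marked <- paste0("#", orthography, "#")
  n <- nchar(marked)
  bigrams <- unique(substring(marked, 1:(n - 1L), 2:n))
  c(letters1, bigrams)
}

# Locate the (single) nucleus run in a DISC string.
# Returns c(start, end) indices or signals an error.
.nucleus_run <- function(phonology, nuclei, what = "phonology") {
  chars <- strsplit(phonology, "", fixed = TRUE)[[1L]]
  v <- chars %in% nuclei
  if (!any(v)) {
    stop("no nucleus found in ", what, " ", sQuote(phonology), call. = FALSE)
  }
  runs <- rle(v)
  if (sum(runs$values) > 1L) {
    stop("multiple nuclei found in ", what, " ", sQuote(phonology), call. = FALSE)
  }
  start <- which(v)[1L]
  end <- max(which(v))
  c(start, end)
}

#' Split a monosyllabic DISC string into demi-syllables
#'
#' A syllable is decomposed into two demi-syllables with the nucleus repeated
#' in both halves: onset + nucleus and nucleus + coda. For `"b8R"` (bear) the
#' halves are `b8` and `8R`. A syllable with an empty onset or coda yields a
#' bare-nucleus half, e.g. `"8R"` splits into `(8, 8R)`.
#'
#' @param phonology DISC string containing exactly one nucleus (one
#'   contiguous run of nucleus symbols).
#' @inheritParams is_vowel
#' @return List with components `first` and `second`.
#' @export
#' @examples
#' split_demisyllables("b8R")   # b8 / 8R
#' split_demisyllables("b{nd")  # b{ / {nd
split_demisyllables <- function(phonology, nuclei = disc_nuclei()) {
  if (!is.character(phonology) || length(phonology) != 1L || !nzchar(phonology)) {
    stop("`phonology` must be a non-empty DISC string", call. = FALSE)
  }
  run <- .nucleus_run(phonology, nuclei)
  list(
    first = substr(phonology, 1L, run[2L]),
    second = substr(phonology, run[1L], nchar(phonology))
  )
}

#' Decompose an orthographic string into onset, vowel cluster and coda
#'
#' The onset is everything before the first orthographic vowel letter, the
#' vowel cluster is the maximal run of vowel letters starting there, and the
#' coda is the remainder. The rhyme (body) is vowel cluster plus coda.
#' `y` counts as a vowel letter only when the string contains no other vowel
#' letter (so `"sky"` parses as `sk` + `y`).
#'
#' @param orthography Lowercase letter string containing at least one vowel
#'   letter.
#' @param vowel_letters Letters treated as orthographic vowels.
#' @return List with components `onset`, `vowel`, `coda` and `rhyme`.
#' @export
#' @examples
#' orthographic_parts("bap")  # b / a / p
#' orthographic_parts("air")  # "" / ai / r
orthographic_parts <- function(orthography,
                               vowel_letters = c("a", "e", "i", "o", "u")) {
  if (!is.character(orthography) || length(orthography) != 1L ||
      !grepl("^[a-z]+$", orthography)) {
    stop("`orthography` must be a non-empty lowercase a-z string", call. = FALSE)
  }
  chars <- strsplit(orthography, "", fixed = TRUE)[[1L]]
  v <- chars %in% vowel_letters
  if (!any(v) && "y" %in% chars) {
    v <- chars == "y"
  }
  if (!any(v)) {
    stop("no orthographic vowel letter in ", sQuote(orthography), call. = FALSE)
  }
  start <- which(v)[1L]
  end <- start
  while (end < length(chars) && v[end + 1L]) end <- end + 1L
  vowel <- substr(orthography, start, end)
  coda <- if (end < length(chars)) substr(orthography, end + 1L, nchar(orthography)) else ""
  list(
    onset = if (start > 1L) substr(orthography, 1L, start - 1L) else "",
    vowel = vowel,
    coda = coda,
    rhyme = paste0(vowel, coda)
  )
}

#' Construct and validate a lexicon
#'
#' A lexicon is a data frame with columns `orthography` (lowercase a-z,
#' unique), `disc` (monosyllabic DISC transcription with exactly one nucleus
#' run), `frequency` (token count, >= 1) and `is_nonword` (logical; added as
#' `FALSE` when absent). Extra columns are preserved.
#'
#' @param x Data frame with at least `orthography`, `disc` and `frequency`.
#' @inheritParams is_vowel
#' @return The validated lexicon, classed `ndra_lexicon`.
#' @export
as_lexicon <- function(x, nuclei = disc_nuclei()) {
  stopifnot(is.data.frame(x))
  required <- c("orthography", "disc", "frequency")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("lexicon is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x$orthography <- as.character(x$orthography)
  x$disc <- as.character(x$disc)
  x$frequency <- as.numeric(x$frequency)
  if (is.null(x$is_nonword)) {
    x$is_nonword <- rep(FALSE, nrow(x))
  } else {
    x$is_nonword <- as.logical(as.integer(x$is_nonword))
  }
  validate_lexicon(x, nuclei = nuclei)
  class(x) <- unique(c("ndra_lexicon", class(x)))
  x
}

#' @rdname as_lexicon
#' @export
validate_lexicon <- function(x, nuclei = disc_nuclei()) {
  bad <- function(i, msg) {
    stop("lexicon entry ", i, " (", sQuote(x$orthography[i]), "): ", msg,
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    if (!grepl("^[a-z]+$", x$orthography[i])) {
      stop("lexicon entry ", i, ": orthography must be lowercase a-z ",
           "(the boundary marker '#' is reserved), got ",
           sQuote(x$orthography[i]), call. = FALSE)
    }
    if (is.na(x$frequency[i]) || x$frequency[i] < 1) {
      bad(i, "frequency must be >= 1")
    }
    ok <- tryCatch({ .nucleus_run(x$disc[i], nuclei); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) bad(i, ok)
  }
  dup <- duplicated(x$orthography)
  if (any(dup)) {
    stop("duplicate orthographies in lexicon: ",
         paste(unique(x$orthography[dup]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a lexicon from a delimited text file
#'
#' The expected format is UTF-8 delimited text with a header row and columns
#' `orthography`, `disc` and `frequency` (optionally `is_nonword` as 0/1).
#' Rows failing validation are reported with their line number.
#'
#' @param path Path to the file.
#' @param sep Field delimiter (tab by default).
#' @inheritParams is_vowel
#' @return An `ndra_lexicon` data frame.
#' @export
read_lexicon <- function(path, sep = "\t", nuclei = disc_nuclei()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty lexicon file: ", path, call. = FALSE)
    return(as_lexicon(data.frame(orthography = character(), disc = character(),
                                 frequency = numeric())))
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    warning("lexicon file has a header but no entries: ", path, call. = FALSE)
    return(as_lexicon(data.frame(orthography = character(), disc = character(),
                                 frequency = numeric())))
  }
  required <- c("orthography", "disc", "frequency")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("lexicon file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  freq <- suppressWarnings(as.numeric(raw$frequency))
  if (anyNA(freq)) {
    stop("malformed frequency at line ", which(is.na(freq))[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  raw$frequency <- freq
  tryCatch(
    as_lexicon(raw, nuclei = nuclei),
    error = function(e) {
      stop("while reading ", path, " (line numbers exclude the header): ",
           conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write a lexicon to a tab-separated file
#'
#' Produces a file that [read_lexicon()] round-trips field-for-field.
#'
#' @param lexicon An `ndra_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- data.frame(
    orthography = lexicon$orthography,
    disc = lexicon$disc,
    frequency = lexicon$frequency,
    is_nonword = as.integer(lexicon$is_nonword)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ndra_lexicon <- function(x, ...) {
  cat("<ndra_lexicon> ", nrow(x), " entries (",
      sum(x$is_nonword), " non-words)\n", sep = "")
  NextMethod()
}
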