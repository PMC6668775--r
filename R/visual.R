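# Visual input interpretation: letter complexity from glyph bitmaps.
#
# The model's front end assumes that visually less prototypical letters take
# longer to decode. Complexity is quantified as a city-block distance of a
# letter's bitmap to the bitmaps of all other letters.

#' Load the packaged glyph bitmaps
#'
#' Reads the deterministic 20x20 binary bitmaps for the letters a-z that
#' ship with the package (a synthetic monospaced typeface stored as
#' PBM-style text blocks). A packaged fixture is used instead of live font
#' rasterization because rasterization is platform-dependent and would make
#' complexity values irreproducible across machines.
#'
#' @param path Path to a glyph archive; defaults to the packaged set.
#' @return Named list of 26 binary 20x20 matrices, classed `ndra_glyphs`.
#' @export
load_fixture_glyphs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glyphs_synthetic_mono_20x20.pbm",
                        package = "ndra", mustWork = TRUE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  ink_line <- grep("^# ink-total:", lines, value = TRUE)
  declared_ink <- if (length(ink_line)) {
    as.integer(sub("^# ink-total:\\s*", "", ink_line[1L]))
  } else {
    NA_integer_
  }
  starts <- grep("^# letter: ", lines)
  glyphs <- list()
  for (s in starts) {
    ch <- sub("^# letter: ", "", lines[s])
    if (lines[s + 1L] != "P1" || lines[s + 2L] != "20 20") {
      stop("corrupted glyph fixture: bad block header for letter ",
           sQuote(ch), call. = FALSE)
    }
    rows <- lines[(s + 3L):(s + 22L)]
    vals <- suppressWarnings(
      lapply(strsplit(rows, " ", fixed = TRUE), as.integer)
    )
    m <- do.call(rbind, vals)
    if (!is.matrix(m) || any(dim(m) != c(20L, 20L)) || anyNA(m) ||
        !all(m %in% c(0L, 1L))) {
      stop("corrupted glyph fixture: letter ", sQuote(ch),
           " is not a 20x20 binary bitmap", call. = FALSE)
    }
    glyphs[[ch]] <- m
  }
  if (!identical(sort(names(glyphs)), letters)) {
    stop("corrupted glyph fixture: expected 26 glyphs a-z, found ",
         length(glyphs), call. = FALSE)
  }
  total_ink <- sum(vapply(glyphs, sum, 1))
  if (!is.na(declared_ink) && total_ink != declared_ink) {
    stop("glyph fixture checksum error: ink-total ", total_ink,
         " does not match declared ", declared_ink, call. = FALSE)
  }
  structure(glyphs[letters], class = "ndra_glyphs")
}

#' @export
print.ndra_glyphs <- function(x, ...) {
  cat("<ndra_glyphs> ", length(x), " glyphs, ",
      nrow(x[[1L]]), "x", ncol(x[[1L]]), " pixels\n", sep = "")
  invisible(x)
}

#' Per-letter visual complexity
#'
#' For each letter `i` the summed city-block (pixel) distance to all other
#' letters is computed:
#' `C_i = f( sum_j sum_k |B_ik - B_jk| )`,
#' where `B` are the binary bitmaps. By default `f` is the square root;
#' `use_sqrt = FALSE` gives the bare sum. Self-distance contributes zero
#' either way. Values are low for letters that look like many others (o, c)
#' and high for visually atypical letters (y, w).
#'
#' @param glyphs A glyph set from [load_fixture_glyphs()].
#' @param use_sqrt Apply the square root to the summed distance (default).
#' @return Named numeric vector of complexities, one per letter.
#' @export
letter_complexity <- function(glyphs, use_sqrt = TRUE) {
  stopifnot(length(glyphs) >= 1L)
  nm <- names(glyphs)
  flat <- vapply(glyphs, as.numeric, numeric(length(glyphs[[1L]])))
  total <- vapply(seq_along(nm), function(i) {
    sum(abs(flat - flat[, i]))
  }, 1)
  names(total) <- nm
  if (use_sqrt) sqrt(total) else total
}

#' Visual complexity of a word
#'
#' The complexity of a letter string is the sum of the per-letter
#' complexities, with repeated letters counted per occurrence. The empty
#' string has complexity 0.
#'
#' @param word Lowercase letter string.
#' @param table Named complexity vector from [letter_complexity()].
#' @return Non-negative scalar.
#' @export
word_complexity <- function(word, table) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(0)
  unknown <- setdiff(chars, names(table))
  if (length(unknown)) {
    stop("letter(s) without a complexity value: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(table[chars])
}
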