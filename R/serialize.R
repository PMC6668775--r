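# Plain-text model serialization: labelled TSV weight matrices plus a JSON
# manifest with parameters and label checksums.

.label_checksum <- function(labels) {
  sum(vapply(labels, function(s) sum(utf8ToInt(s)), 1)) %% 2147483647
}

.write_matrix <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     col.names = NA, fileEncoding = "UTF-8")
}

.read_matrix <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE,
                              fileEncoding = "UTF-8"))
}

#' Write a trained model to a directory
#'
#' Serializes the weight matrices as labelled tab-separated text, the
#' lexicon in its native format, and a JSON manifest holding the
#' parameters, the nucleus inventory, the letter-complexity table and
#' label checksums used to verify integrity on reload.
#'
#' @param model A trained `ndra_model`.
#' @param dir Output directory (created if necessary).
#' @return The directory, invisibly.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "ndra_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_matrix(model$o2l, file.path(dir, "o2l.tsv"))
  .write_matrix(model$p2l, file.path(dir, "p2l.tsv"))
  if (!is.null(model$sublex)) {
    .write_matrix(model$sublex, file.path(dir, "sublex.tsv"))
  }
  write_lexicon(model$lexicon, file.path(dir, "lexicon.tsv"))
  manifest <- list(
    params = unclass(model$params),
    nuclei = model$nuclei,
    complexity = as.list(model$complexity),
    include_nonwords = any(model$training$is_nonword),
    checksums = list(
      o2l_rows = .label_checksum(rownames(model$o2l)),
      o2l_cols = .label_checksum(colnames(model$o2l)),
      p2l_rows = .label_checksum(rownames(model$p2l)),
      p2l_cols = .label_checksum(colnames(model$p2l))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trained model from a directory
#'
#' Restores a model written by [write_model()], verifying the label
#' checksums recorded in the manifest.
#'
#' @param dir Directory written by [write_model()].
#' @return An `ndra_model`.
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  o2l <- .read_matrix(file.path(dir, "o2l.tsv"))
  p2l <- .read_matrix(file.path(dir, "p2l.tsv"))
  cs <- manifest$checksums
  if (.label_checksum(rownames(o2l)) != cs$o2l_rows ||
      .label_checksum(colnames(o2l)) != cs$o2l_cols ||
      .label_checksum(rownames(p2l)) != cs$p2l_rows ||
      .label_checksum(colnames(p2l)) != cs$p2l_cols) {
    stop("model directory ", dir, " failed label checksum verification",
         call. = FALSE)
  }
  sublex_path <- file.path(dir, "sublex.tsv")
  lexicon <- read_lexicon(file.path(dir, "lexicon.tsv"),
                          nuclei = manifest$nuclei)
  params <- do.call(ndra_params, manifest$params)
  nuclei <- manifest$nuclei
  include_nonwords <- isTRUE(manifest$include_nonwords)
  entries <- .training_entries(lexicon, include_nonwords)
  splits <- lapply(entries$disc, split_demisyllables, nuclei = nuclei)
  parts <- lapply(entries$orthography, orthographic_parts)
  training <- data.frame(
    orthography = entries$orthography,
    disc = entries$disc,
    frequency = entries$frequency,
    is_nonword = entries$is_nonword,
    lexeme = lexeme_of(entries$orthography),
    demi1 = vapply(splits, `[[`, "", "first"),
    demi2 = vapply(splits, `[[`, "", "second"),
    onset = vapply(parts, `[[`, "", "onset"),
    vowel = vapply(parts, `[[`, "", "vowel"),
    coda = vapply(parts, `[[`, "", "coda"),
    rhyme = vapply(parts, `[[`, "", "rhyme"),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      o2l = o2l, p2l = p2l,
      sublex = if (file.exists(sublex_path)) .read_matrix(sublex_path),
      lexicon = lexicon, training = training,
      demis1 = sort(unique(training$demi1), method = "radix"),
      demis2 = sort(unique(training$demi2), method = "radix"),
      params = params, nuclei = nuclei,
      complexity = unlist(manifest$complexity)
    ),
    class = "ndra_model"
  )
}
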