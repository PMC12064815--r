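#' Class vocabulary with a dedicated noise class
#'
#' An ordered list of species codes plus one non-bird "noise" class
#' (clips with no birds present). The ordering defines the logit index of
#' every class and is part of the checkpoint contract.
#'
#' @param species_ids Character vector of unique species codes.
#' @param noise_class Code used for the noise class (default `"noise"`).
#' @return A `class_vocabulary` with fields `classes` (species followed by
#'   the noise class) and `noise_class_index`.
#' @export
class_vocabulary <- function(species_ids, noise_class = "noise") {
  species_ids <- as.character(species_ids)
  if (anyDuplicated(species_ids)) stop("species ids must be unique")
  if (noise_class %in% species_ids) stop("noise class code clashes with a species id")
  classes <- c(species_ids, noise_class)
  structure(
    list(classes = classes, species_ids = species_ids,
         noise_class = noise_class, noise_class_index = length(classes)),
    class = "class_vocabulary"
  )
}

#' @export
print.class_vocabulary <- function(x, ...) {
  cat(sprintf("<class_vocabulary: %d species + noise class '%s' (index %d)>\n",
              length(x$species_ids), x$noise_class, x$noise_class_index))
  invisible(x)
}

#' Number of classes (species + noise)
#' @param vocab A `class_vocabulary`.
#' @export
n_classes <- function(vocab) length(vocab$classes)

#' Weak recording-level annotation
#'
#' One primary species, zero or more secondary (background) species, no
#' timing information. Secondary annotations are typically incomplete in
#' real archives; the synthetic generator models that incompleteness.
#' A noise-only recording has `primary_species` equal to the vocabulary's
#' noise class.
#'
#' @param recording_id Identifier string.
#' @param primary_species Primary species code (or the noise-class code).
#' @param secondary_species Character vector of secondary codes (may be empty).
#' @param source Free-text source tag (e.g. `"focal"`, `"soundscape"`).
#' @return A `recording_annotation`.
#' @export
recording_annotation <- function(recording_id, primary_species,
                                 secondary_species = character(), source = "focal") {
  secondary_species <- as.character(secondary_species)
  if (primary_species %in% secondary_species)
    stop("primary species must not be repeated in secondary species")
  structure(
    list(recording_id = as.character(recording_id),
         primary_species = as.character(primary_species),
         secondary_species = secondary_species, source = source),
    class = "recording_annotation"
  )
}

#' Build a per-class target vector from a weak annotation
#'
#' Single-label mode one-hots the primary species. Multi-label mode sets 1 at
#' the primary and, if `use_secondary`, at each secondary species. Noise-only
#' recordings are one-hot on the noise class in both modes. Secondary labels
#' carry full weight 1 (no down-weighting).
#'
#' @param annotation A `recording_annotation`.
#' @param vocab A `class_vocabulary`.
#' @param use_secondary Include secondary species (multi-label mode only)?
#' @param mode `"single"` or `"multi"`.
#' @return Numeric target vector of length `n_classes(vocab)`.
#' @export
build_target <- function(annotation, vocab, use_secondary = TRUE,
                         mode = c("multi", "single")) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "recording_annotation"),
            inherits(vocab, "class_vocabulary"))
  codes <- c(annotation$primary_species,
             if (mode == "multi" && use_secondary) annotation$secondary_species)
  unknown <- setdiff(codes, vocab$classes)
  if (length(unknown))
    stop("unknown species code(s): ", paste(unknown, collapse = ", "))
  y <- numeric(n_classes(vocab))
  if (annotation$primary_species == vocab$noise_class) {
    y[vocab$noise_class_index] <- 1
    return(y)
  }
  y[match(codes, vocab$classes)] <- 1
  y
}

#' Filter species by minimum recording count
#'
#' Retains species with at least `min_recordings` recordings (inclusive
#' threshold, default 10). Order-preserving and deterministic.
#'
#' @param counts Named integer vector or data.frame with columns `species`
#'   and `count`.
#' @param min_recordings Inclusive minimum (default 10).
#' @return Character vector of retained species codes.
#' @export
curate_species <- function(counts, min_recordings = 10L) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$species)
  }
  stopifnot(all(counts >= 0))
  names(counts)[counts >= min_recordings]
}

#' Data-availability regime of a species
#'
#' `< 50` recordings is low, `50-200` (inclusive) medium, `> 200` high.
#'
#' @param count Non-negative recording count (vectorised).
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
data_regime <- function(count) {
  stopifnot(all(count >= 0))
  ifelse(count < 50, "low", ifelse(count <= 200, "medium", "high"))
}

#' Write annotations to CSV
#'
#' Dialect: columns `recording_id`, `primary_species`, `secondary_species`
#' (semicolon-joined), `split`, `source`.
#'
#' @param annotations List of `recording_annotation`.
#' @param path Output CSV path.
#' @param split Optional character vector of split labels (recycled).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, split = "train") {
  df <- data.frame(
    recording_id = vapply(annotations, `[[`, "", "recording_id"),
    primary_species = vapply(annotations, `[[`, "", "primary_species"),
    secondary_species = vapply(annotations, function(a)
      paste(a$secondary_species, collapse = ";"), ""),
    split = rep_len(split, length(annotations)),
    source = vapply(annotations, `[[`, "", "source"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read annotations from CSV
#' @param path CSV in the dialect of [write_annotations()].
#' @return List with `annotations` (list of `recording_annotation`) and
#'   `split` (character vector).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(secondary_species = "character"))
  anns <- lapply(seq_len(nrow(df)), function(i) {
    sec <- df$secondary_species[i]
    sec <- if (is.na(sec) || sec == "") character() else strsplit(sec, ";")[[1]]
    recording_annotation(df$recording_id[i], df$primary_species[i], sec,
                         source = if ("source" %in% names(df)) df$source[i] else "focal")
  })
  list(annotations = anns,
       split = if ("split" %in% names(df)) df$split else rep("train", nrow(df)))
}

#' Save / load a class vocabulary as JSON
#'
#' The JSON file stores the explicit class ordering; logit index i of any
#' checkpoint maps to `classes[i]`.
#'
#' @param vocab A `class_vocabulary`.
#' @param path JSON path.
#' @return `path` invisibly (write) or a `class_vocabulary` (read).
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(species_ids = vocab$species_ids, noise_class = vocab$noise_class),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  class_vocabulary(x$species_ids, noise_class = x$noise_class[[1]])
}
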