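#' Read a long-format annotation table
#'
#' Annotations are stored in long format: one row per (instance, annotator)
#' pair, absent pairs meaning the annotator did not label that instance.
#' Labels are 0-based class indices in `{0, ..., class_count - 1}`.
#'
#' @param path Path to a CSV file with header
#'   `instance_id,annotator_id,label`.
#' @param class_count Number of classes `K` (>= 2); labels are validated
#'   against it.
#'
#' @return A tibble with columns `instance_id` (character), `annotator_id`
#'   (character) and `label` (integer), in file order.
#' @export
read_annotations <- function(path, class_count) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "crowdattn_io_error")
  }
  required <- c("instance_id", "annotator_id", "label")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 3 || !identical(header[1:3], required)) {
    abort(
      paste0("annotation file must have header 'instance_id,annotator_id,label', got: ",
             paste(header, collapse = ",")),
      class = "crowdattn_format_error"
    )
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(
    instance_id = readr::col_character(),
    annotator_id = readr::col_character(),
    label = readr::col_integer()
  ))
  validate_annotations(tbl, class_count)
  tbl
}

validate_annotations <- function(annotations, class_count) {
  stopifnot(is.data.frame(annotations))
  check_class_count(class_count)
  lab <- annotations$label
  if (anyNA(lab) || any(lab < 0L) || any(lab >= class_count)) {
    bad <- which(is.na(lab) | lab < 0L | lab >= class_count)[1]
    abort(
      sprintf("label %s at row %d is outside {0..%d}",
              as.character(lab[bad]), bad, class_count - 1L),
      class = "crowdattn_validation_error"
    )
  }
  dup <- duplicated(annotations[c("instance_id", "annotator_id")])
  if (any(dup)) {
    d <- annotations[which(dup)[1], ]
    abort(
      sprintf("duplicate (instance, annotator) pair: (%s, %s)",
              d$instance_id, d$annotator_id),
      class = "crowdattn_format_error"
    )
  }
  invisible(annotations)
}

check_class_count <- function(class_count) {
  if (!is.numeric(class_count) || length(class_count) != 1 ||
      is.na(class_count) || class_count < 2 || class_count != round(class_count)) {
    abort("class_count must be a single integer >= 2",
          class = "crowdattn_validation_error")
  }
  invisible(as.integer(class_count))
}

#' Read a feature table
#'
#' @param path CSV with header `instance_id,f1,...,fD`; one row per instance.
#'   Row order defines the instance order of the dataset.
#' @return A tibble with `instance_id` (character) followed by numeric
#'   feature columns.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("feature file not found: ", path), class = "crowdattn_io_error")
  }
  tbl <- readr::read_csv(path, col_types = readr::cols(
    instance_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (names(tbl)[1] != "instance_id" || ncol(tbl) < 2) {
    abort("feature file must have header 'instance_id,f1,...,fD'",
          class = "crowdattn_format_error")
  }
  tbl
}

#' Read a gold-label table
#'
#' @param path CSV with header `instance_id,label`.
#' @param class_count Number of classes for validation.
#' @return A tibble with `instance_id` (character) and `label` (integer).
#' @export
read_gold <- function(path, class_count) {
  if (!file.exists(path)) {
    abort(paste0("gold file not found: ", path), class = "crowdattn_io_error")
  }
  check_class_count(class_count)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    instance_id = readr::col_character(),
    label = readr::col_integer()
  ))
  if (!identical(names(tbl)[1:2], c("instance_id", "label"))) {
    abort("gold file must have header 'instance_id,label'",
          class = "crowdattn_format_error")
  }
  if (any(tbl$label < 0L | tbl$label >= class_count)) {
    abort("gold label outside {0..K-1}", class = "crowdattn_validation_error")
  }
  tbl
}

#' Assemble a validated crowdsourced dataset
#'
#' Bundles features, long-format annotations and (optionally) gold labels
#' into a `crowd_dataset`. Every instance must carry at least one
#' annotation; the feature table is the single source of truth for the
#' instance set and ordering.
#'
#' @param features Data frame with `instance_id` plus numeric feature
#'   columns (one row per instance).
#' @param annotations Data frame of `instance_id`, `annotator_id`, `label`
#'   records (any row order).
#' @param gold Optional data frame with `instance_id`, `label`; must cover
#'   exactly the feature instances.
#' @param class_count Number of classes `K` (>= 2).
#' @param annotator_count Number of annotators `W`; inferred as the number
#'   of distinct annotator ids when `NULL`.
#'
#' @return An object of class `crowd_dataset`: a list with `features`,
#'   `annotations`, `gold` (or `NULL`), `class_count`, `annotator_count`.
#' @export
assemble_dataset <- function(features, annotations, gold = NULL, class_count,
                             annotator_count = NULL) {
  class_count <- check_class_count(class_count)
  features <- tibble::as_tibble(features)
  if (names(features)[1] != "instance_id" || ncol(features) < 2) {
    abort("features must have an 'instance_id' column followed by feature columns",
          class = "crowdattn_validation_error")
  }
  features$instance_id <- as.character(features$instance_id)
  if (anyDuplicated(features$instance_id)) {
    abort("duplicate instance_id in features", class = "crowdattn_validation_error")
  }
  fmat <- as.matrix(features[-1])
  if (!is.numeric(fmat) || any(!is.finite(fmat))) {
    abort("all feature values must be finite numbers",
          class = "crowdattn_validation_error")
  }
  annotations <- tibble::as_tibble(annotations)
  annotations$instance_id <- as.character(annotations$instance_id)
  annotations$annotator_id <- as.character(annotations$annotator_id)
  annotations$label <- as.integer(annotations$label)
  validate_annotations(annotations, class_count)
  unknown <- setdiff(annotations$instance_id, features$instance_id)
  if (length(unknown) > 0) {
    abort(paste0("annotation refers to unknown instance: ", unknown[1]),
          class = "crowdattn_validation_error")
  }
  unlabeled <- setdiff(features$instance_id, annotations$instance_id)
  if (length(unlabeled) > 0) {
    abort(
      sprintf("every instance needs at least one annotation; %d have none (e.g. %s)",
              length(unlabeled), unlabeled[1]),
      class = "crowdattn_validation_error"
    )
  }
  if (!is.null(gold)) {
    gold <- tibble::as_tibble(gold)
    gold$instance_id <- as.character(gold$instance_id)
    gold$label <- as.integer(gold$label)
    if (nrow(gold) != nrow(features) ||
        !setequal(gold$instance_id, features$instance_id)) {
      abort("gold labels must cover exactly the feature instances",
            class = "crowdattn_validation_error")
    }
    if (any(gold$label < 0L | gold$label >= class_count)) {
      abort("gold label outside {0..K-1}", class = "crowdattn_validation_error")
    }
    gold <- gold[match(features$instance_id, gold$instance_id), ]
  }
  w_seen <- length(unique(annotations$annotator_id))
  if (is.null(annotator_count)) {
    annotator_count <- w_seen
  } else if (annotator_count < w_seen) {
    abort("annotator_count smaller than the number of distinct annotator ids",
          class = "crowdattn_validation_error")
  }
  structure(
    list(
      features = features,
      annotations = annotations,
      gold = gold,
      class_count = class_count,
      annotator_count = as.integer(annotator_count)
    ),
    class = "crowd_dataset"
  )
}

#' @export
print.crowd_dataset <- function(x, ...) {
  cat(sprintf(
    "<crowd_dataset> %d instances x %d features, %d classes, %d annotators, %d annotations%s\n",
    nrow(x$features), ncol(x$features) - 1L, x$class_count, x$annotator_count,
    nrow(x$annotations), if (is.null(x$gold)) "" else ", gold labels present"
  ))
  invisible(x)
}

#' Feature matrix of a crowd dataset
#' @param dataset A `crowd_dataset`.
#' @return Numeric matrix (instances x features), rownames = instance ids.
#' @export
feature_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "crowd_dataset"))
  m <- as.matrix(dataset$features[-1])
  rownames(m) <- dataset$features$instance_id
  m
}

#' One-hot encode a class label
#'
#' @param label 0-based class index (vectorised).
#' @param class_count Number of classes `K`.
#' @return For scalar input, a length-`K` 0/1 vector with a single 1 at
#'   position `label + 1`; for a vector input, a matrix with one row per
#'   label.
#' @export
one_hot <- function(label, class_count) {
  class_count <- check_class_count(class_count)
  label <- as.integer(label)
  if (anyNA(label) || any(label < 0L) || any(label >= class_count)) {
    abort(sprintf("label outside {0..%d}", class_count - 1L),
          class = "crowdattn_validation_error")
  }
  m <- matrix(0, nrow = length(label), ncol = class_count)
  m[cbind(seq_along(label), label + 1L)] <- 1
  if (length(label) == 1L) drop(m) else m
}

#' Write a crowd dataset to its CSV triplet
#'
#' Writes `features.csv`, `annotations.csv` and (when gold labels are
#' present) `gold.csv` under `dir`; full-precision numeric output so a
#' write/read cycle is lossless.
#'
#' @param dataset A `crowd_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix, e.g. `"train_"`.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_crowd_dataset <- function(dataset, dir, prefix = "") {
  stopifnot(inherits(dataset, "crowd_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(features = file.path(dir, paste0(prefix, "features.csv")),
             annotations = file.path(dir, paste0(prefix, "annotations.csv")))
  readr::write_csv(dataset$features, paths[["features"]])
  readr::write_csv(dataset$annotations, paths[["annotations"]])
  if (!is.null(dataset$gold)) {
    paths <- c(paths, gold = file.path(dir, paste0(prefix, "gold.csv")))
    readr::write_csv(dataset$gold, paths[["gold"]])
  }
  invisible(paths)
}

#' Read a crowd dataset from its CSV triplet
#'
#' @param dir Directory holding the files written by [write_crowd_dataset()].
#' @param class_count Number of classes `K`.
#' @param prefix Filename prefix used at write time.
#' @return A `crowd_dataset`.
#' @export
read_crowd_dataset <- function(dir, class_count, prefix = "") {
  features <- read_features(file.path(dir, paste0(prefix, "features.csv")))
  annotations <- read_annotations(file.path(dir, paste0(prefix, "annotations.csv")),
                                  class_count)
  gold_path <- file.path(dir, paste0(prefix, "gold.csv"))
  gold <- if (file.exists(gold_path)) read_gold(gold_path, class_count) else NULL
  assemble_dataset(features, annotations, gold = gold, class_count = class_count)
}
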