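# Tab-separated readers/writers for OTU tables, sample metadata and
# dissimilarity matrices. All tables are samples-as-rows with the sample
# identifier in the first column.

#' Read an OTU count table
#'
#' Expects tab-separated text: first row OTU identifiers, first column sample
#' identifiers, integer cells. Ragged rows, non-integer cells and duplicate
#' identifiers are rejected with the offending row/column named.
#'
#' @param path file path.
#' @return wide OTU tibble (`sample_id` + integer count columns).
#' @export
read_otu_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0(
      "Malformed OTU table at row ", probs$row[1], ", column ", probs$col[1],
      ": ", probs$expected[1]
    ))
  }
  check_that(ncol(raw) >= 2, "OTU table needs a sample column plus counts.")
  names(raw)[1] <- "sample_id"
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0(
      "Duplicate sample id: ",
      paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort(paste0(
      "Duplicate OTU id: ",
      paste(unique(names(raw)[-1][duplicated(names(raw)[-1])]), collapse = ", ")
    ))
  }
  for (col in names(raw)[-1]) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad)) {
      abort(paste0(
        "Non-integer count in column '", col, "', row ", bad[1],
        " (value '", raw[[col]][bad[1]], "')."
      ))
    }
    raw[[col]] <- as.integer(round(v))
  }
  raw
}

#' Write an OTU table as tab-separated text
#'
#' @param tbl wide OTU tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(tbl, path) {
  otu_matrix(tbl, check = FALSE) # shape validation
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Requires tab-separated text with columns `sample_id`, `substrate_bin`,
#' `incubation`, `is_control`. `substrate_bin` is checked against the closed
#' vocabulary ([substrate_bins()]); control samples must carry
#' `substrate_bin = "control"`.
#'
#' @param path file path.
#' @return tibble of validated metadata records.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", substrate_bin = "c", incubation = "i", is_control = "l"
  ), progress = FALSE)
  required <- c("sample_id", "substrate_bin", "incubation", "is_control")
  missing <- setdiff(required, names(md))
  check_that(
    length(missing) == 0,
    paste0("Metadata is missing column(s): ", paste(missing, collapse = ", "))
  )
  validate_metadata(md[required])
}

validate_metadata <- function(md) {
  bad <- setdiff(unique(md$substrate_bin), SUBSTRATE_BINS)
  check_that(
    length(bad) == 0,
    paste0(
      "Unknown substrate_bin '", bad[1], "'; must be one of: ",
      paste(SUBSTRATE_BINS, collapse = ", ")
    )
  )
  check_that(
    all(is.na(md$incubation) | md$incubation %in% 1:5),
    "`incubation` must be 1..5 or missing."
  )
  check_that(!any(is.na(md$is_control)), "`is_control` must be TRUE/FALSE.")
  check_that(
    all(!md$is_control | md$substrate_bin == "control"),
    "Control samples must have substrate_bin = 'control'."
  )
  check_that(
    !anyDuplicated(md$sample_id),
    "Duplicate sample_id in metadata."
  )
  as_tibble(md)
}

#' Write per-sample metadata
#' @param md metadata tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  validate_metadata(md)
  readr::write_tsv(md, path, progress = FALSE)
  invisible(path)
}

#' Write a dissimilarity matrix as square tab-separated text
#'
#' Header row and first column carry the sample identifiers.
#'
#' @param d a [stats::dist] or symmetric matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  m <- as_dissimilarity_matrix(d)
  out <- dplyr::bind_cols(
    tibble(sample_id = rownames(m)),
    as_tibble(m, .name_repair = "minimal")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a square dissimilarity matrix
#' @param path file path.
#' @return a [stats::dist] object.
#' @export
read_dissimilarity <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "d",
    sample_id = "c"
  ), progress = FALSE)
  m <- as.matrix(raw[-1])
  rownames(m) <- raw$sample_id
  check_that(
    identical(rownames(m), colnames(m)),
    "Row and column sample identifiers disagree."
  )
  stats::as.dist(as_dissimilarity_matrix(m))
}
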