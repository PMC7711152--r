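# Internal helpers shared across modules.

# Closed vocabulary for sample substrate bins. Water samples (filtered and
# unfiltered) collapse to "background"; calcite/dolomite/HVD collapse to
# "carbonate"; sequencing negative controls are "control".
SUBSTRATE_BINS <- c(
  "background", "PUR", "carbonate", "silica", "mixed", "steel",
  "organic", "control"
)

#' Coerce a wide OTU tibble to a count matrix
#'
#' OTU tables travel as tibbles with a `sample_id` character column followed by
#' one numeric column per OTU. This extracts the numeric matrix (samples x
#' OTUs) with dimnames.
#'
#' @param tbl a wide OTU tibble.
#' @param check validate counts (non-negative integers) in addition to shape.
#' @return numeric matrix, rownames = sample ids, colnames = OTU ids.
#' @keywords internal
#' @noRd
otu_matrix <- function(tbl, check = TRUE) {
  if (!is.data.frame(tbl) || !"sample_id" %in% names(tbl)) {
    abort("An OTU table must be a data frame with a 'sample_id' column.")
  }
  ids <- as.character(tbl$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate sample_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  if (ncol(m) == 0) m <- matrix(numeric(0), nrow = nrow(tbl), ncol = 0)
  if (!is.numeric(m)) abort("OTU columns must be numeric.")
  if (anyDuplicated(colnames(m))) abort("Duplicate OTU ids in table.")
  rownames(m) <- ids
  if (check) {
    if (anyNA(m)) abort("OTU counts must not contain missing values.")
    if (any(m < 0)) abort("OTU counts must be non-negative.")
  }
  m
}

# Inverse of otu_matrix().
matrix_to_otu_tbl <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

# Integerness check that tolerates double storage of whole numbers.
is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}

# Stop unless `cond`, with a message naming the violated requirement.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards, so the generators never disturb the session stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
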