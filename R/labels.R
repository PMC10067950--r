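#' Mastoiditis category and symmetry-grade label calculus
#'
#' Each ear is labelled with an ordinal mastoiditis category: 0 normal
#' (clear air cells), 1 mild (some haziness), 2 severe (total haziness with
#' sclerosis), 3 postoperative (mastoidectomy state). Postoperative ears are
#' inherently asymmetric and are excluded from symmetry evaluation. The
#' symmetry grade of a subject is the absolute difference of the two ears'
#' categories, restricted to categories 0-2.
#'
#' @name labels
NULL

CATEGORY_NAMES <- c("normal", "mild", "severe", "postoperative")

check_category <- function(cat, what = "category") {
  if (length(cat) != 1L || is.na(cat) || cat != as.integer(cat) ||
      !(cat %in% 0:3)) {
    stop(what, " must be a single integer in 0..3")
  }
  as.integer(cat)
}

#' Symmetry grade of a bilateral category pair
#'
#' `grade = |right - left|` for categories in `{0, 1, 2}`: grade 0 when both
#' ears share a category, grade 1 for a one-stage difference, grade 2 for
#' normal versus severe. Symmetric in its arguments.
#'
#' @param right,left ear categories (integers in 0..2).
#' @return integer grade in 0..2.
#' @export
symmetry_grade <- function(right, left) {
  right <- check_category(right, "right category")
  left <- check_category(left, "left category")
  if (right == 3L || left == 3L) {
    stop("postoperative (category 3) ears are excluded from symmetry evaluation")
  }
  abs(right - left)
}

#' Dichotomize a true ear category
#'
#' Negative if normal, positive if mild or severe. Category 3 is excluded.
#'
#' @param cat ear category (integer in 0..2).
#' @return `"negative"` or `"positive"`.
#' @export
dichotomize_label <- function(cat) {
  cat <- check_category(cat)
  if (cat == 3L) stop("postoperative (category 3) ears are excluded")
  if (cat == 0L) "negative" else "positive"
}

#' Dichotomize a predicted category probability vector
#'
#' The prediction is negative when the highest-probability category is
#' normal, positive when it is mild or severe. An exact tie between normal
#' and an abnormal category is resolved toward positive (screening favours
#' sensitivity). The continuous positive-class score used for ROC analysis
#' is `1 - p(normal) = p(mild) + p(severe)`.
#'
#' @param probs length-3 non-negative vector summing to 1 (tolerance 1e-6),
#'   ordered (normal, mild, severe).
#' @return list with `outcome` (`"negative"`/`"positive"`) and `score`
#'   (positive-class score).
#' @export
dichotomize_prediction <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 3L) {
    stop("probs must be a numeric 3-vector")
  }
  if (any(probs < 0)) stop("probs must be non-negative")
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  outcome <- if (probs[1] > max(probs[2:3])) "negative" else "positive"
  list(outcome = outcome, score = 1 - probs[1])
}

#' Read a bilateral label table
#'
#' Parses a delimited label file with columns `subject_id`,
#' `right_category`, `left_category` (categories as integers 0-3). Rows with
#' a postoperative (category 3) ear are retained and flagged `excluded`
#' rather than dropped, so exclusion counts remain auditable; their grade is
#' `NA`.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `subject_id`, `right`, `left`, `grade`,
#'   `excluded`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "right_category", "left_category")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("label table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  parse_cat <- function(x, col, row) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v) || v != as.integer(v) || !(v %in% 0:3)) {
      stop("row ", row, ": ", col, " value '", x,
           "' is not a category in 0..3")
    }
    as.integer(v)
  }
  n <- nrow(df)
  right <- integer(n); left <- integer(n)
  for (i in seq_len(n)) {
    right[i] <- parse_cat(df$right_category[i], "right_category", i)
    left[i] <- parse_cat(df$left_category[i], "left_category", i)
  }
  excluded <- right == 3L | left == 3L
  grade <- ifelse(excluded, NA_integer_, abs(right - left))
  data.frame(subject_id = as.character(df$subject_id),
             right = right, left = left,
             grade = as.integer(grade), excluded = excluded,
             stringsAsFactors = FALSE)
}
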