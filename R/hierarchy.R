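#' Generalization hierarchies
#'
#' A generalization hierarchy defines, for every base value of a
#' quasi-identifier, one label per generalization level; level 0 is the
#' value itself and higher levels cover increasingly large parts of the
#' attribute's domain (e.g. exact age, ten-year interval, `*`). The
#' hierarchy must be tree-structured: two base values that share a label
#' at some level share labels at all coarser levels.
#'
#' `hierarchy()` builds the object from a character matrix or data frame
#' whose rows are base values and whose columns are levels 0, 1, ....
#' Along the way it computes the per-label leaf counts that the loss-based
#' quality model needs (`leaf_count[[level + 1]][label]` = number of base
#' values the label covers).
#'
#' @param rows character matrix or data frame, one row per base value,
#'   `height` columns; column 1 must equal the base value.
#' @param attribute name of the quasi-identifier.
#' @return An object of class `hierarchy`: a list with elements
#'   `attribute`, `height`, `labels` (character matrix, rownames = base
#'   values), `leaf_count` (list of named integer vectors, one per level)
#'   and `domain_size`.
#' @examples
#' h <- hierarchy(rbind(c("male", "*"), c("female", "*")), "sex")
#' h$height                    # 2
#' generalize_value(h, "male", 1)  # "*"
#' @export
hierarchy <- function(rows, attribute) {
  if (is.data.frame(rows))
    rows <- as.matrix(rows)
  if (!is.matrix(rows))
    rows <- matrix(rows, nrow = 1L)
  storage.mode(rows) <- "character"
  if (nrow(rows) < 1L || ncol(rows) < 1L)
    stop("hierarchy for '", attribute, "' needs at least one row and level")
  if (anyNA(rows))
    stop("hierarchy for '", attribute, "' contains missing labels")
  base <- rows[, 1L]
  dup <- base[duplicated(base)]
  if (length(dup))
    stop("hierarchy for '", attribute, "' repeats base value(s): ",
         paste(unique(dup), collapse = ", "))
  height <- ncol(rows)
  # tree consistency: a level-l label determines the level-(l+1) label
  for (l in seq_len(height - 1L)) {
    parent <- tapply(rows[, l + 1L], rows[, l],
                     function(v) length(unique(v)))
    if (any(parent > 1L)) {
      bad <- names(parent)[parent > 1L][1L]
      stop("hierarchy for '", attribute, "' is not tree-structured: label '",
           bad, "' at level ", l - 1L,
           " generalizes to several distinct labels at level ", l)
    }
  }
  dimnames(rows) <- list(base, paste0("level", seq_len(height) - 1L))
  leaf_count <- lapply(seq_len(height), function(l) {
    tab <- table(rows[, l])
    stats::setNames(as.integer(tab), names(tab))
  })
  structure(
    list(attribute = as.character(attribute),
         height = height,
         labels = rows,
         leaf_count = leaf_count,
         domain_size = length(base)),
    class = "hierarchy")
}

#' @export
print.hierarchy <- function(x, ...) {
  cat("Generalization hierarchy '", x$attribute, "': ",
      x$domain_size, " base values, height ", x$height, "\n", sep = "")
  top <- unique(x$labels[, x$height])
  cat("  top level: ", paste(utils::head(top, 5), collapse = ", "),
      if (length(top) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a generalization hierarchy file
#'
#' The file dialect follows the convention of widely used de-identification
#' tooling so published hierarchies can be dropped in: semicolon-separated,
#' no header, one row per base value, columns = levels 0 to height-1,
#' UTF-8, optional double quoting. Values are kept exactly as read (case
#' and whitespace sensitive).
#'
#' @param file path or connection.
#' @param attribute attribute name; defaults to the file name stripped of
#'   a `.hierarchy.csv` / `.csv` suffix.
#' @return a [hierarchy()] object.
#' @export
read_hierarchy <- function(file, attribute = NULL) {
  if (is.null(attribute)) {
    attribute <- if (is.character(file))
      sub("\\.hierarchy$", "", sub("\\.csv$", "", basename(file)))
    else "attr"
  }
  rows <- tryCatch(
    utils::read.table(file, sep = ";", header = FALSE, quote = "\"",
                      colClasses = "character", stringsAsFactors = FALSE,
                      comment.char = "", strip.white = FALSE,
                      encoding = "UTF-8"),
    error = function(e)
      stop("malformed hierarchy file for '", attribute, "': ",
           conditionMessage(e)))
  hierarchy(as.matrix(rows), attribute)
}

#' Write a generalization hierarchy file
#'
#' Inverse of [read_hierarchy()]; round-trips exactly.
#'
#' @param h a [hierarchy()].
#' @param file path or connection.
#' @export
write_hierarchy <- function(h, file) {
  utils::write.table(h$labels, file, sep = ";", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Generalize a single value
#'
#' Looks up the label of `value` at the given level; level 0 is the
#' identity.
#'
#' @param h a [hierarchy()].
#' @param value base value (must be in the hierarchy's domain).
#' @param level integer in `0 ... height - 1`.
#' @return character scalar.
#' @export
generalize_value <- function(h, value, level) {
  if (level < 0L || level >= h$height)
    stop("level ", level, " outside 0..", h$height - 1L,
         " for attribute '", h$attribute, "'")
  i <- match(value, rownames(h$labels))
  if (is.na(i))
    stop("value '", value, "' not in the domain of attribute '",
         h$attribute, "'")
  unname(h$labels[i, level + 1L])
}

#' Build a lattice spec from hierarchies
#'
#' @param hierarchies list of [hierarchy()] objects.
#' @return a [lattice_spec()] with the hierarchies' heights and names.
#' @export
lattice_spec_for <- function(hierarchies) {
  lattice_spec(vapply(hierarchies, function(h) h$height, integer(1)),
               vapply(hierarchies, function(h) h$attribute, character(1)))
}

#' Read and validate a quasi-identifier dataset
#'
#' The dataset is a plain comma-separated file with a header row naming the
#' quasi-identifiers, matching the hierarchies' attribute names in order.
#' Every value must appear as a base value of its attribute's hierarchy —
#' an unknown value is a linkage error and is reported with attribute, row
#' and value rather than silently normalized.
#'
#' @param file path or connection.
#' @param hierarchies list of [hierarchy()] objects, in column order.
#' @return a data frame of character columns, validated; zero rows allowed.
#' @export
read_qidata <- function(file, hierarchies) {
  df <- utils::read.csv(file, colClasses = "character", check.names = FALSE,
                        stringsAsFactors = FALSE, comment.char = "",
                        strip.white = FALSE, encoding = "UTF-8")
  validate_qidata(df, hierarchies)
}

#' @rdname read_qidata
#' @param data a data frame of character columns to validate in place.
#' @export
validate_qidata <- function(data, hierarchies) {
  wanted <- vapply(hierarchies, function(h) h$attribute, character(1))
  if (!identical(names(data), wanted))
    stop("dataset header (", paste(names(data), collapse = ", "),
         ") does not match hierarchy attributes (",
         paste(wanted, collapse = ", "), ") in order")
  for (i in seq_along(hierarchies)) {
    vals <- as.character(data[[i]])
    bad <- which(!(vals %in% rownames(hierarchies[[i]]$labels)))
    if (length(bad))
      stop("attribute '", wanted[i], "', row ", bad[1L], ": value '",
           vals[bad[1L]], "' has no hierarchy row")
    data[[i]] <- vals
  }
  data
}

#' Write a (possibly anonymized) dataset
#'
#' Same comma-separated dialect as [read_qidata()]. Suppressed records stay
#' in the output with every cell replaced by the suppression token, so the
#' row count always equals the input's.
#'
#' @param data data frame of character columns.
#' @param file path or connection.
#' @export
write_qidata <- function(data, file) {
  utils::write.csv(data, file, quote = FALSE, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Apply a policy to a dataset
#'
#' Full-domain generalization: every value of attribute `i` is replaced by
#' its hierarchy label at level `policy[i]`. Records flagged in
#' `suppressed` are emitted as rows of the suppression token.
#'
#' @param data validated quasi-identifier data frame.
#' @param hierarchies list of [hierarchy()] objects.
#' @param policy integer policy vector.
#' @param suppressed logical vector of length `nrow(data)` (default none).
#' @param token suppression token (default `"*"`).
#' @return data frame of the same shape as `data`.
#' @export
generalize_data <- function(data, hierarchies, policy,
                            suppressed = rep(FALSE, nrow(data)),
                            token = "*") {
  spec <- lattice_spec_for(hierarchies)
  policy <- validate_policy(policy, spec)
  stopifnot(length(suppressed) == nrow(data))
  out <- data
  for (i in seq_along(hierarchies)) {
    h <- hierarchies[[i]]
    idx <- match(data[[i]], rownames(h$labels))
    out[[i]] <- unname(h$labels[idx, policy[i] + 1L])
  }
  if (any(suppressed))
    out[suppressed, ] <- token
  out
}
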