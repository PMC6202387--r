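#' Person-by-variable study table
#'
#' The universal input container of the package: a numeric persons x
#' variables matrix (continuous scores, ordinal items coded `0..K-1`,
#' binary variables coded 0/1, `NA` allowed), a two-level group label per
#' person, and per-variable type and role flags.
#'
#' @param values numeric matrix or data.frame, persons in rows. Column
#'   names are the variable labels.
#' @param group vector of group labels, one per row. Comparison operations
#'   require exactly two levels.
#' @param var_types character vector, one per column, each one of
#'   `"continuous"`, `"ordinal"`, `"binary"`.
#' @param var_roles character vector, one per column, each one of
#'   `"resilience_factor"`, `"distress"`, `"item"`. Defaults to
#'   `"resilience_factor"` for every column.
#'
#' @return An object of class `rf_study_table` with elements `values`
#'   (numeric matrix), `group` (factor), `var_types`, `var_roles`.
#' @export
#' @examples
#' x <- study_table(matrix(rnorm(20), 10, 2,
#'                         dimnames = list(NULL, c("a", "b"))),
#'                  group = rep(c("g1", "g2"), each = 5),
#'                  var_types = c("continuous", "continuous"))
study_table <- function(values, group,
                        var_types = rep("continuous", ncol(values)),
                        var_roles = rep("resilience_factor", ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  if (length(group) != nrow(values))
    stop("`group` must have one entry per row of `values`")
  if (length(var_types) != ncol(values) || length(var_roles) != ncol(values))
    stop("`var_types` and `var_roles` must have one entry per column")
  ok_types <- c("continuous", "ordinal", "binary")
  if (!all(var_types %in% ok_types))
    stop("var_types must be one of: ", paste(ok_types, collapse = ", "))
  ok_roles <- c("resilience_factor", "distress", "item")
  if (!all(var_roles %in% ok_roles))
    stop("var_roles must be one of: ", paste(ok_roles, collapse = ", "))
  for (j in which(var_types == "binary")) {
    v <- values[, j]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("binary column '", colnames(values)[j],
           "' contains values outside {0, 1, NA}")
  }
  names(var_types) <- names(var_roles) <- colnames(values)
  structure(list(values = values, group = factor(group),
                 var_types = var_types, var_roles = var_roles),
            class = "rf_study_table")
}

#' @export
print.rf_study_table <- function(x, ...) {
  cat("Study table:", nrow(x$values), "persons x", ncol(x$values),
      "variables\n")
  cat("Groups:", paste(sprintf("%s (n = %d)", levels(x$group),
                               as.vector(table(x$group))),
                       collapse = ", "), "\n")
  tt <- table(x$var_types)
  cat("Types:", paste(names(tt), tt, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Subset the variables of a study table
#'
#' @param table an [study_table()] object.
#' @param vars character vector of column names (or a role name such as
#'   `"resilience_factor"` to keep every column with that role).
#' @return An `rf_study_table` with the selected columns.
#' @export
subset_vars <- function(table, vars) {
  stopifnot(inherits(table, "rf_study_table"))
  if (length(vars) == 1 && vars %in% c("resilience_factor", "distress", "item"))
    vars <- names(table$var_roles)[table$var_roles == vars]
  missing_v <- setdiff(vars, colnames(table$values))
  if (length(missing_v))
    stop("unknown variables: ", paste(missing_v, collapse = ", "))
  study_table(table$values[, vars, drop = FALSE], table$group,
              table$var_types[vars], table$var_roles[vars])
}

#' Extract one group's rows as a single-group study table
#'
#' @param table an [study_table()] object.
#' @param level a group level.
#' @return An `rf_study_table` containing only that group's rows.
#' @export
table_group <- function(table, level) {
  stopifnot(inherits(table, "rf_study_table"))
  if (!level %in% levels(table$group))
    stop("unknown group level '", level, "'")
  keep <- table$group == level
  study_table(table$values[keep, , drop = FALSE],
              as.character(table$group[keep]),
              table$var_types, table$var_roles)
}

#' Write / read a study table as CSV plus a JSON sidecar
#'
#' The CSV holds the data with a `group` column; variable types and roles
#' go to `<path>.meta.json`.
#'
#' @param table an [study_table()] object.
#' @param path CSV file path.
#' @return `write_study_table` returns `path` invisibly; `read_study_table`
#'   returns the reconstructed `rf_study_table`.
#' @export
write_study_table <- function(table, path) {
  stopifnot(inherits(table, "rf_study_table"))
  df <- data.frame(group = as.character(table$group), table$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(var_types = as.list(table$var_types),
               var_roles = as.list(table$var_roles))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  vals <- as.matrix(df[setdiff(names(df), "group")])
  study_table(vals, df$group,
              unlist(meta$var_types)[colnames(vals)],
              unlist(meta$var_roles)[colnames(vals)])
}
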