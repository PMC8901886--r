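#' Age-by-year tables
#'
#' The universal grid of the life-cycle models: a real-valued quantity
#' (abundance, weight-at-age, maturity, survey index, landings, mortality)
#' indexed by integer age class (columns) and calendar year (rows).  An
#' `age_year_table` is a plain numeric matrix with strictly increasing
#' integer year rownames and age colnames plus `quantity` and `unit`
#' attributes; missing cells are `NA`.
#'
#' @param values numeric matrix, years in rows and ages in columns.
#' @param years integer vector of calendar years (strictly increasing).
#' @param ages integer vector of age classes (strictly increasing,
#'   0-based biological ages).
#' @param quantity short label for what the table holds (e.g. `"weight"`).
#' @param unit unit string (e.g. `"kg"`, `"individuals"`).
#' @return an object of class `age_year_table`.
#' @examples
#' tab <- age_year_table(matrix(1:6, 3, 2), years = 2000:2002, ages = 0:1)
#' ayt_years(tab)
#' @export
age_year_table <- function(values, years, ages, quantity = "value", unit = "") {
  values <- as.matrix(values)
  years <- as.integer(years)
  ages <- as.integer(ages)
  if (nrow(values) != length(years) || ncol(values) != length(ages)) {
    stop("dimension mismatch: values must be length(years) x length(ages)")
  }
  if (anyDuplicated(years) || is.unsorted(years, strictly = TRUE)) {
    stop("years must be unique and strictly increasing")
  }
  if (anyDuplicated(ages) || is.unsorted(ages, strictly = TRUE)) {
    stop("ages must be unique and strictly increasing")
  }
  if (any(is.infinite(values))) stop("values must be finite where present")
  storage.mode(values) <- "double"
  dimnames(values) <- list(year = as.character(years), age = as.character(ages))
  structure(values,
    quantity = quantity, unit = unit,
    class = c("age_year_table", "matrix", "array")
  )
}

#' @rdname age_year_table
#' @param x an `age_year_table`.
#' @export
ayt_years <- function(x) as.integer(rownames(x))

#' @rdname age_year_table
#' @export
ayt_ages <- function(x) as.integer(colnames(x))

#' @export
print.age_year_table <- function(x, ...) {
  cat(sprintf(
    "age_year_table '%s'%s: %d years (%s-%s) x %d ages (%s-%s)\n",
    attr(x, "quantity"),
    if (nzchar(attr(x, "unit"))) paste0(" [", attr(x, "unit"), "]") else "",
    nrow(x), rownames(x)[1], rownames(x)[nrow(x)],
    ncol(x), colnames(x)[1], colnames(x)[ncol(x)]
  ))
  print(unclass(structure(x, quantity = NULL, unit = NULL)), ...)
  invisible(x)
}

#' Read an age-by-year table from CSV
#'
#' Expects the dialect `year,a0,a1,...`: first column calendar year, one
#' column per age class, empty fields for missing cells.
#'
#' @param path file to read.
#' @param quantity,unit labels attached to the returned table.
#' @return an [age_year_table()].
#' @export
read_age_year_table <- function(path, quantity = "value", unit = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || tolower(names(df)[1]) != "year") {
    stop("expected header 'year,a<age>,...' in ", path)
  }
  years_chr <- df[[1]]
  years <- suppressWarnings(as.integer(years_chr))
  if (anyNA(years)) {
    stop("non-integer year value in ", path, ": ", years_chr[which(is.na(years))[1]])
  }
  if (anyDuplicated(years)) {
    stop("duplicated year ", years[anyDuplicated(years)], " in ", path)
  }
  age_lab <- sub("^a", "", names(df)[-1])
  ages <- suppressWarnings(as.integer(age_lab))
  if (anyNA(ages)) stop("non-integer age column '", names(df)[-1][which(is.na(ages))[1]], "' in ", path)
  vals <- matrix(NA_real_, nrow(df), length(ages))
  for (j in seq_along(ages)) {
    cell <- df[[j + 1L]]
    empty <- !nzchar(trimws(cell))
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric cell '%s' at row %d, column %s in %s",
        cell[bad[1]], bad[1], names(df)[j + 1L], path
      ))
    }
    vals[, j] <- ifelse(empty, NA_real_, num)
  }
  ord <- order(years)
  age_year_table(vals[ord, , drop = FALSE], years[ord], ages,
    quantity = quantity, unit = unit
  )
}

#' Write an age-by-year table to CSV
#'
#' Inverse of [read_age_year_table()]; full double precision, missing
#' cells as empty fields.
#'
#' @param x an `age_year_table`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_age_year_table <- function(x, path) {
  stopifnot(inherits(x, "age_year_table"))
  cells <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  cells[is.na(x)] <- ""
  df <- data.frame(year = rownames(x), cells, check.names = FALSE)
  names(df) <- c("year", paste0("a", colnames(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read/write an annual series (year,value CSV)
#'
#' @param path file path.
#' @param value_name header of the value column.
#' @return named numeric vector (names are years).
#' @export
read_year_series <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L || tolower(names(df)[1]) != "year") {
    stop("expected header 'year,<value>' in ", path)
  }
  yrs <- as.integer(df[[1]])
  if (anyDuplicated(yrs)) stop("duplicated year in ", path)
  stats::setNames(as.numeric(df[[2]]), yrs)[order(yrs)]
}

#' @rdname read_year_series
#' @param x named numeric vector (names are years).
#' @export
write_year_series <- function(x, path, value_name = "value") {
  df <- data.frame(
    year = as.integer(names(x)),
    value = format(unname(x), digits = 17, trim = TRUE, scientific = FALSE)
  )
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
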