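#' Read a response/covariate dataset from CSV
#'
#' Loads a response matrix (header row of item names, one row per person,
#' integer cells) and optionally a covariate table (a `person_id` column
#' plus named covariate columns), validating both: no missing cells,
#' integer categories starting at 0, and matching row counts. Load errors
#' name the offending row and column.
#'
#' @param responses_path CSV file of responses.
#' @param covariates_path optional CSV file of covariates.
#' @param schema optional list: `dichotomize = TRUE` recodes response 0 to 0
#'   and every other category to 1 (the usual "no" versus any-other-response
#'   rule for dichotomizing polytomous scales); `kinds` is a named character
#'   vector declaring each covariate's scale (`"continuous"`, `"ordered"`,
#'   `"unordered"`) -- scales are declared, never inferred from storage
#'   type; `ordered_levels` is a named list giving the level order of
#'   ordered covariates.
#' @return list of class `"irt_dataset"`: `resp`, `covariates`, `kinds`,
#'   `n_obs`, `source`.
#' @export
read_dataset <- function(responses_path, covariates_path = NULL,
                         schema = list()) {
  raw <- utils::read.csv(responses_path, check.names = FALSE)
  m <- as.matrix(raw)
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing response cell at row ", idx[1L], ", column '",
         colnames(m)[idx[2L]], "'")
  }
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(m))) |
                   suppressWarnings(as.numeric(m)) %% 1 != 0 |
                   suppressWarnings(as.numeric(m)) < 0)[1L]
    stop("non-integer response at row ", (bad - 1L) %% nrow(m) + 1L,
         ", column '", colnames(m)[(bad - 1L) %/% nrow(m) + 1L], "'")
  }
  storage.mode(m) <- "integer"
  if (isTRUE(schema$dichotomize)) m[] <- as.integer(m > 0L)

  cov <- NULL
  kinds <- schema$kinds
  if (!is.null(covariates_path)) {
    cov <- utils::read.csv(covariates_path, check.names = FALSE)
    if (nrow(cov) != nrow(m))
      stop("row-count mismatch: ", nrow(m), " response rows but ",
           nrow(cov), " covariate rows")
    if (any(is.na(cov))) {
      idx <- which(is.na(cov), arr.ind = TRUE)[1L, ]
      stop("missing covariate cell at row ", idx[1L], ", column '",
           colnames(cov)[idx[2L]], "'")
    }
    for (nm in names(schema$ordered_levels %||% list())) {
      lev <- schema$ordered_levels[[nm]]
      obs <- unique(as.character(cov[[nm]]))
      extra <- setdiff(obs, lev)
      if (length(extra))
        stop("covariate '", nm, "': observed value '", extra[1L],
             "' is not among the declared ordered levels")
      cov[[nm]] <- factor(cov[[nm]], levels = lev, ordered = TRUE)
    }
  }
  structure(list(resp = m, covariates = cov, kinds = kinds,
                 n_obs = nrow(m),
                 source = c(responses = responses_path,
                            covariates = covariates_path %||% NA_character_)),
            class = "irt_dataset")
}

#' Write a response matrix or score matrix to CSV
#'
#' Round-trip safe writers: [read_dataset()] on the written responses
#' recovers the matrix exactly, and score matrices keep their parameter
#' labels as a header for external auditing.
#'
#' @param x response matrix or score matrix.
#' @param path output CSV path.
#' @export
write_responses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
write_scores <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Serialize a test result to a metadata-complete list
#'
#' Contains everything needed to re-run the computation: model, functional,
#' statistic, p-value and its method, tested parameters, seed/replication
#' information, and package version.
#'
#' @param result an `"invtest"` object.
#' @return a named list (JSON-ready).
#' @export
result_metadata <- function(result) {
  list(functional = result$functional,
       statistic = result$statistic,
       p_value = result$p_value,
       pvalue_method = result$pvalue_method,
       model = result$model %||% NA_character_,
       pars = result$pars,
       n_obs = result$n_obs,
       n_pars = result$n_pars,
       trim = result$trim,
       location = result$location_value %||% result$location,
       package_version = as.character(utils::packageVersion("scoreflux")))
}
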