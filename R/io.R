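#' Read and write system files
#'
#' Systems are stored as JSON or YAML with keys `labels`, `matrix`
#' (row-major, row = affected type), `growth_rates` and an `orientation`
#' field naming the matrix convention, or as CSV whose first line is a
#' comment declaring the orientation followed by one row per affected type
#' (`label`, `growth_rate`, one column per acting type). The format is
#' chosen from the file extension (`.json`, `.yaml`/`.yml`, `.csv`).
#' Numbers round-trip at full double precision.
#'
#' @param sys an [eco_game_system()].
#' @param path file path.
#' @return `read_system()` returns an [eco_game_system()];
#'   `write_system()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_system(fixture_system("pd_equal"), f)
#' read_system(f)
#' @export
write_system <- function(sys, path) {
  sys <- as_system(sys)
  ext <- tolower(tools::file_ext(path))
  payload <- list(
    orientation = "row=affected,col=acting",
    labels = sys$labels,
    matrix = unname(lapply(seq_len(nrow(sys$A)), function(i) unname(sys$A[i, ]))),
    growth_rates = unname(sys$r))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path, precision = 17)
  } else if (ext == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# lvgames system; orientation: row=affected,col=acting", con)
    df <- data.frame(label = sys$labels, growth_rate = sys$r,
                     stringsAsFactors = FALSE)
    M <- as.data.frame(sys$A)
    names(M) <- paste0("a_", sys$labels)
    utils::write.csv(format(cbind(df, M), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported system file extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    obj <- yaml::read_yaml(path)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    A <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(A) <- "double"
    return(eco_game_system(A, as.numeric(df$growth_rate), labels = df$label))
  } else {
    stop("unsupported system file extension: .", ext)
  }
  A <- do.call(rbind, lapply(obj$matrix, function(row) as.numeric(unlist(row))))
  eco_game_system(A, as.numeric(unlist(obj$growth_rates)),
                  labels = as.character(unlist(obj$labels)))
}

#' Read and write trajectory CSV files
#'
#' Columns are `t` followed by one column per type; comment-prefixed header
#' lines record the kind of dynamics that produced the trajectory. Values
#' are written with 17 significant digits so round-trips are lossless.
#'
#' @param traj an `lv_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns an `lv_trajectory` (without the
#'   originating system); `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lvgames trajectory; dynamics_kind: ",
                    traj$dynamics_kind), con)
  df <- data.frame(t = traj$times)
  for (j in seq_len(ncol(traj$states))) df[[traj$labels[j]]] <- traj$states[, j]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub(".*dynamics_kind:\\s*", "", first)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  new_trajectory(df$t, as.matrix(df[, -1, drop = FALSE]), kind,
                 labels = names(df)[-1])
}
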