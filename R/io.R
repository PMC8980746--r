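#' Read a replicate growth-curve CSV
#'
#' Two dialects are supported. `"long"` has columns
#' `time_h,replicate,density_cfu_per_ml`, one row per measurement. `"wide"`
#' has a `time_h` column followed by one column per replicate (any names,
#' e.g. `rep1,rep2,rep3`). All replicates must share the same time grid and
#' all densities must be strictly positive; offending rows are named in the
#' error.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @param label condition label to attach; defaults to the file name.
#' @param induction_time induction time (h) to attach, or `NA`.
#' @return A [growth_dataset()].
#' @seealso [write_growth_csv()]
#' @export
read_growth_csv <- function(path, dialect = c("long", "wide"),
                            label = NULL, induction_time = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label))
    label <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("time_h", "replicate", "density_cfu_per_ml")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "))
    bad <- which(!is.finite(df$density_cfu_per_ml) |
                   df$density_cfu_per_ml <= 0)
    if (length(bad))
      stop("non-positive density at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    df <- df[order(df$replicate, df$time_h), ]
    reps <- unique(df$replicate)
    times <- sort(unique(df$time_h))
    counts <- matrix(NA_real_, nrow = length(reps), ncol = length(times),
                     dimnames = list(as.character(reps), NULL))
    for (r in seq_along(reps)) {
      sub <- df[df$replicate == reps[r], ]
      if (nrow(sub) != length(times) || any(sub$time_h != times))
        stop("replicate '", reps[r], "' does not cover the shared time grid")
      counts[r, ] <- sub$density_cfu_per_ml
    }
  } else {
    if (names(df)[1] != "time_h")
      stop("wide dialect requires first column 'time_h'")
    if (ncol(df) < 2L) stop("wide dialect requires replicate columns")
    ord <- order(df$time_h)
    df <- df[ord, ]
    times <- df$time_h
    counts <- t(as.matrix(df[, -1, drop = FALSE]))
    bad <- which(!is.finite(counts) | counts <= 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("non-positive density for replicate '",
           rownames(counts)[bad[1, 1]], "' at time ",
           times[bad[1, 2]], " h in ", path)
  }
  growth_dataset(times, counts, label = label,
                 induction_time = induction_time)
}

#' Write a replicate growth-curve CSV
#'
#' @param dataset a [growth_dataset()].
#' @param path output file.
#' @param dialect `"long"` or `"wide"`; see [read_growth_csv()].
#' @return `path` invisibly.
#' @export
write_growth_csv <- function(dataset, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "growth_dataset"))
  if (dialect == "long") {
    reps <- rownames(dataset$counts)
    df <- data.frame(
      time_h = rep(dataset$times, times = nrow(dataset$counts)),
      replicate = rep(reps, each = length(dataset$times)),
      density_cfu_per_ml = as.vector(t(dataset$counts)))
  } else {
    df <- data.frame(time_h = dataset$times, t(dataset$counts))
    names(df)[-1] <- rownames(dataset$counts)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' Header `time_h,density_cfu_per_ml,capacity_cfu_per_ml`, preceded by a
#' comment line recording the realised activation time, activation density
#' and capacity latency.
#'
#' @param trajectory a `growth_trajectory` from [simulate_growth()].
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "growth_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# activation_time_h=%s activation_density_cfu_per_ml=%s delay_h=%s",
    format(trajectory$activation_time),
    format(trajectory$activation_density),
    format(trajectory$delay)), con)
  write.csv(as.data.frame(trajectory), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return A data frame with columns `time_h`, `density_cfu_per_ml`,
#'   `capacity_cfu_per_ml`.
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an experiment manifest
#'
#' A manifest is a CSV with columns `label,file,role,induction_time` that
#' maps condition labels to per-condition growth CSVs (paths relative to
#' the manifest). `role` is one of `off`, `uninduced`, `on`, `induced`,
#' `qs`; `induction_time` is in hours or `none`. Files are read with
#' [read_growth_csv()] (dialect auto-detected from the header).
#'
#' @param path manifest CSV path.
#' @return A named list of [growth_dataset()] objects with a `"roles"`
#'   attribute (named character vector label -> role).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "file", "role", "induction_time")
  if (!all(need %in% names(man)))
    stop("manifest requires columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$label))
    stop("duplicate labels in manifest")
  base <- dirname(path)
  out <- vector("list", nrow(man))
  names(out) <- man$label
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$file[i])
    ti <- suppressWarnings(as.numeric(man$induction_time[i]))
    header <- names(read.csv(f, nrows = 1, comment.char = "#"))
    dialect <- if (identical(header[1:2], c("time_h", "replicate")) &&
                   "density_cfu_per_ml" %in% header) "long" else "wide"
    out[[i]] <- read_growth_csv(f, dialect, label = man$label[i],
                                induction_time = ti)
  }
  attr(out, "roles") <- setNames(tolower(man$role), man$label)
  out
}
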