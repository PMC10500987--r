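# XVG energy-series boundary.  Dialect: lines starting with '#' or '@' are
# metadata, data rows are whitespace-separated numbers.  Files may be in
# kcal/mol or kJ/mol; everything is kcal/mol in memory (factor 4.184).

.kj2kcal <- function(x) x / KCAL_TO_KJ
.kcal2kj <- function(x) x * KCAL_TO_KJ

#' Read a per-window energy series from an XVG file
#'
#' Frame-wise reactant-state and product-state energies for one FEP window.
#' Lines beginning with `#` or `@` are metadata; `# lambda <value>` and
#' `# window <index>` comments, when present, are attached as columns.
#'
#' @param path File to read.
#' @param columns Named integer vector mapping column positions, e.g.
#'   `c(time = 1, eps1 = 2, eps2 = 3)`; `eps1` and `eps2` are required,
#'   `time` and `V` optional.
#' @param units `"kcal"` or `"kJ"`; kJ/mol values are converted to kcal/mol
#'   at read time.
#' @return A tibble with the mapped columns (energies in kcal/mol) plus
#'   `step`, and `window`/`lambda` columns when the metadata carries them.
#' @export
read_energy_xvg <- function(path, columns = c(time = 1, eps1 = 2, eps2 = 3),
                            units = c("kcal", "kJ")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "evbfep_io_error")
  }
  if (!all(c("eps1", "eps2") %in% names(columns))) {
    rlang::abort("`columns` must map at least eps1 and eps2",
                 class = "evbfep_io_error")
  }
  lines <- readLines(path)
  meta <- grepl("^[#@]", lines) | !nzchar(trimws(lines))
  lambda <- NA_real_
  window <- NA_integer_
  for (ln in lines[meta]) {
    if (grepl("^#\\s*lambda\\s", ln)) {
      lambda <- as.numeric(sub("^#\\s*lambda\\s+", "", ln))
    }
    if (grepl("^#\\s*window\\s", ln)) {
      window <- as.integer(sub("^#\\s*window\\s+", "", ln))
    }
  }
  data_idx <- which(!meta)
  if (!length(data_idx)) {
    rlang::abort(paste0("no data rows in ", path), class = "evbfep_io_error")
  }
  toks <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncols <- lengths(toks)
  need <- max(columns)
  bad <- which(ncols != ncols[1] | ncols < need)
  if (length(bad)) {
    rlang::abort(sprintf("ragged or short data row at %s line %d",
                         path, data_idx[bad[1]]),
                 class = "evbfep_io_error")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(toks))),
                nrow = length(toks), byrow = TRUE)
  if (any(is.na(mat[, columns]))) {
    row <- which(apply(is.na(mat[, columns, drop = FALSE]), 1, any))[1]
    rlang::abort(sprintf("non-numeric cell at %s line %d",
                         path, data_idx[row]),
                 class = "evbfep_io_error")
  }
  out <- tibble::as_tibble(as.data.frame(mat[, columns, drop = FALSE]))
  names(out) <- names(columns)
  conv <- intersect(c("eps1", "eps2", "V"), names(out))
  if (units == "kJ") out[conv] <- lapply(out[conv], .kj2kcal)
  out$step <- seq_len(nrow(out))
  if (!is.na(window)) out <- dplyr::mutate(out, window = window, .before = 1)
  if (!is.na(lambda)) {
    out <- dplyr::mutate(out, lambda = lambda,
                         .after = if (!is.na(window)) "window" else NULL)
  }
  out
}

#' Write a per-window energy series as XVG
#'
#' @param frames Frame tibble with `eps1`, `eps2` (kcal/mol) and optionally
#'   `step`; single-window data.
#' @param path Output file.
#' @param lambda,window Metadata written as `# lambda` / `# window` comments;
#'   default to the frame columns/attributes when present.
#' @param units Output units (`"kcal"` or `"kJ"`).
#' @return `path`, invisibly.
#' @export
write_energy_xvg <- function(frames, path, lambda = NULL, window = NULL,
                             units = c("kcal", "kJ")) {
  units <- match.arg(units)
  .assert_frames(frames)
  if (is.null(lambda)) {
    lambda <- if ("lambda" %in% names(frames)) frames$lambda[1]
              else attr(frames, "lambda")
  }
  if (is.null(window) && "window" %in% names(frames)) {
    window <- frames$window[1]
  }
  e1 <- frames$eps1
  e2 <- frames$eps2
  if (units == "kJ") { e1 <- .kcal2kj(e1); e2 <- .kcal2kj(e2) }
  step <- if ("step" %in% names(frames)) frames$step else seq_len(nrow(frames))
  hdr <- c("# evbfep energy series",
           sprintf("# units %s/mol", if (units == "kJ") "kJ" else "kcal"),
           if (!is.null(window)) sprintf("# window %d", as.integer(window)),
           if (!is.null(lambda) && !is.na(lambda))
             sprintf("# lambda %.15g", lambda),
           "@ xaxis label \"frame\"",
           "@ yaxis label \"energy\"")
  rows <- sprintf("%d %.15g %.15g", as.integer(step), e1, e2)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write / read a whole windowed energy set as one XVG file per window
#'
#' `write_energy_series()` splits a multi-window frame tibble into
#' `window_###.xvg` files; `read_energy_series()` reads every such file in a
#' directory back into the interchange frame layout used by the samplers and
#' analysers (synthetic and engine-derived data are interchangeable
#' downstream).
#'
#' @param frames Frame tibble with `window`, `lambda`, `eps1`, `eps2`.
#' @param dir Directory for the per-window files (created if needed).
#' @param units File units.
#' @return `write_energy_series()`: the file paths, invisibly.
#'   `read_energy_series()`: the combined frame tibble.
#' @export
write_energy_series <- function(frames, dir, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  .assert_frames(frames, need_window = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(frames, frames$window), function(w) {
    p <- file.path(dir, sprintf("window_%03d.xvg", w$window[1]))
    write_energy_xvg(w, p, units = units)
    p
  }, character(1))
  invisible(unname(paths))
}

#' @rdname write_energy_series
#' @export
read_energy_series <- function(dir, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  files <- sort(list.files(dir, pattern = "^window_\\d+\\.xvg$",
                           full.names = TRUE))
  if (!length(files)) {
    rlang::abort(paste0("no window_###.xvg files in ", dir),
                 class = "evbfep_io_error")
  }
  out <- purrr::map_dfr(files, read_energy_xvg,
                        columns = c(time = 1, eps1 = 2, eps2 = 3),
                        units = units)
  if (!all(c("window", "lambda") %in% names(out))) {
    rlang::abort("window files lack `# window` / `# lambda` metadata",
                 class = "evbfep_io_error")
  }
  out <- dplyr::transmute(out, window = as.integer(.data$window),
                          lambda = .data$lambda,
                          step = as.integer(.data$time),
                          eps1 = .data$eps1, eps2 = .data$eps2)
  dplyr::arrange(out, .data$window, .data$step)
}

#' Write a free-energy profile / reaction summary as TSV
#'
#' @param profile An `evb_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  stopifnot(inherits(profile, "evb_profile"))
  df <- as.data.frame(profile)
  utils::write.table(format(df, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_table
#' @param summary An `evb_summary` (optionally with `sd`/`sem` columns).
#' @export
write_summary_table <- function(summary, path) {
  utils::write.table(format(as.data.frame(summary), digits = 12,
                            scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
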