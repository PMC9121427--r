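# Plain-text interchange: trajectory CSV, branch archives, configuration.
#
# CSV dialect: comma separated, '.' decimal, '#'-prefixed header lines
# carrying metadata as key=value pairs; numbers are written with 17
# significant digits so write -> read round-trips at full double precision.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

meta_header <- function(meta) {
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) paste(fmt_num(v), collapse = ",") else
      paste(as.character(v), collapse = ",")
    sprintf("# %s=%s", k, v)
  }, character(1))
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", body, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(body, 1, eq - 1))
    val <- trimws(substr(body, eq + 1, nchar(body)))
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' Write / read a kinematic trajectory CSV
#'
#' Comma-separated values with `#`-prefixed `key=value` header lines that
#' record the frame rate, noise level, seed, stride time and model
#' parameters; full double precision, so the round trip reproduces the
#' object exactly.
#'
#' @param traj trajectory data frame (see [generate_fixture()]).
#' @param path file path.
#' @return `write_trajectory` the path invisibly; `read_trajectory` the
#'   trajectory data frame with its metadata attributes restored.
#' @export
write_trajectory <- function(traj, path) {
  traj <- check_trajectory(traj)
  meta <- list(format = "slipgait-trajectory-v1")
  for (k in c("frame_rate", "sigma", "seed", "stride_time", "provenance")) {
    v <- attr(traj, k)
    if (!is.null(v)) meta[[k]] <- v
  }
  pp <- attr(traj, "params")
  if (!is.null(pp))
    meta$params <- unlist(pp[c("m", "lo", "g", "k", "omega", "phi_l",
                               "phi_r")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  writeLines(paste(names(traj), collapse = ","), con)
  body <- apply(vapply(traj, fmt_num, character(nrow(traj))), 1, paste,
                collapse = ",")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- parse_meta(lines[hdr])
  if (!identical(meta$format, "slipgait-trajectory-v1"))
    stop("not a slipgait trajectory file (missing format header): ", path)
  body <- lines[!hdr]
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("t", traj_channels)
  if (!all(need %in% cols))
    stop("trajectory file lacks required columns ",
         paste(setdiff(need, cols), collapse = ", "),
         " (line ", which(!hdr)[1], ")")
  vals <- strsplit(body[-1], ",")
  bad <- which(lengths(vals) != length(cols))
  if (length(bad))
    stop("malformed row at line ", which(!hdr)[1 + bad[1]], ": expected ",
         length(cols), " fields")
  M <- matrix(as.numeric(unlist(vals)), ncol = length(cols), byrow = TRUE)
  out <- as.data.frame(M)
  names(out) <- cols
  for (k in c("frame_rate", "sigma", "seed", "stride_time", "provenance"))
    if (!is.null(meta[[k]])) attr(out, k) <- meta[[k]]
  if (!is.null(meta$params)) {
    pv <- meta$params
    attr(out, "params") <- slip_params(m = pv[1], lo = pv[2], g = pv[3],
                                       k = pv[4], omega = pv[5],
                                       phi_l = pv[6], phi_r = pv[7])
  }
  check_trajectory(out)
}

gait_to_list <- function(g) {
  list(s = as.list(g$s), times = g$times, label = g$label,
       energy = g$energy, apex_speed = g$apex_speed,
       stride_length = g$stride_length, average_speed = g$average_speed,
       duty_factor = g$duty_factor, residual_norm = g$residual_norm,
       admissible = g$admissible,
       params = g$params[c("m", "lo", "g", "k", "omega", "phi_l", "phi_r")],
       units = list(length = "lo", time = "sqrt(lo/g)",
                    speed = "sqrt(g*lo)", stiffness = "m*g/lo",
                    angle = "rad"))
}

#' Write / read a branch archive
#'
#' JSON archives store every solution (reduced state, event times, label,
#' energy), the termination reasons and the model parameters; the CSV
#' format is a flat table with one row per solution.
#'
#' @param branch a `slip_branch`.
#' @param path file path.
#' @param format `"json"` or `"csv"` (chosen from the file extension by
#'   default).
#' @return `write_branch` the path invisibly; `read_branch` a
#'   `slip_branch`.
#' @export
write_branch <- function(branch, path, format = NULL) {
  stopifnot(inherits(branch, "slip_branch"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else "csv"
  if (format == "json") {
    obj <- list(format = "slipgait-branch-v1",
                params = branch$params[c("m", "lo", "g", "k", "omega",
                                         "phi_l", "phi_r")],
                termination = branch$termination, closed = branch$closed,
                candidates = if (branch$n) unname(apply(branch$X, 1,
                                                        as.list))
                else list(),
                labels = branch$info$label)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- cbind(as.data.frame(branch$X), label = branch$info$label,
                E = branch$info$E)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(meta_header(list(
      format = "slipgait-branch-v1",
      params = unlist(branch$params[c("m", "lo", "g", "k", "omega",
                                      "phi_l", "phi_r")]),
      termination_start = branch$termination$start %||% "NA",
      termination_end = branch$termination$end %||% "NA")), con)
    writeLines(paste(names(df), collapse = ","), con)
    num <- vapply(df[seq_len(ncol(df) - 2)], fmt_num,
                  character(nrow(df)))
    body <- apply(cbind(num, df$label, vapply(df$E, fmt_num,
                                              character(1))), 1,
                  paste, collapse = ",")
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_branch
#' @export
read_branch <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else "csv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "slipgait-branch-v1"))
      stop("not a slipgait branch file: ", path)
    p <- do.call(slip_params, as.list(obj$params))
    X <- if (length(obj$candidates)) {
      cd <- obj$candidates       # data frame after simplification
      as.matrix(as.data.frame(cd)[candidate_names])
    } else NULL
    runs <- list(pos = list(U = X, attrs = NULL,
                            termination = obj$termination$end %||% "NA",
                            closed = isTRUE(obj$closed)))
    br <- assemble_branch(runs, p)
    br$termination <- obj$termination
    br
  } else {
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    meta <- parse_meta(lines[hdr])
    if (!identical(meta$format, "slipgait-branch-v1"))
      stop("not a slipgait branch file: ", path)
    body <- lines[!hdr]
    cols <- strsplit(body[1], ",")[[1]]
    vals <- strsplit(body[-1], ",")
    bad <- which(lengths(vals) != length(cols))
    if (length(bad))
      stop("malformed row at line ", which(!hdr)[1 + bad[1]])
    M <- do.call(rbind, vals)
    X <- apply(M[, seq_len(11), drop = FALSE], 2, as.numeric)
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    pv <- meta$params
    p <- slip_params(m = pv[1], lo = pv[2], g = pv[3], k = pv[4],
                     omega = pv[5], phi_l = pv[6], phi_r = pv[7])
    br <- assemble_branch(list(pos = list(U = X, attrs = NULL,
                                          termination = meta$termination_end,
                                          closed = FALSE)), p)
    br$termination <- list(start = meta$termination_start,
                           end = meta$termination_end)
    br
  }
}

config_keys <- c("k", "omega", "phi_l", "phi_r", "m", "lo", "g", "rtol",
                 "atol", "speed_cap", "amp_cap", "premature_wtol",
                 "frame_rate", "sigma", "seed")

#' Load a flat key=value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments.
#' Recognized keys are the model parameters (`k, omega, phi_l, phi_r, m,
#' lo, g`), solver settings (`rtol, atol, speed_cap, amp_cap,
#' premature_wtol`) and fixture settings (`frame_rate, sigma, seed`).
#'
#' @param path file path.
#' @return named list of values; component `params` holds a
#'   [slip_params()] assembled from the model-parameter keys.
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    eq <- regexpr("=", lines[i], fixed = TRUE)
    if (eq < 0) stop("line ", i, ": expected 'key = value'")
    key <- trimws(substr(lines[i], 1, eq - 1))
    if (!key %in% config_keys)
      stop("line ", i, ": unknown key '", key, "' (valid keys: ",
           paste(config_keys, collapse = ", "), ")")
    val <- suppressWarnings(as.numeric(trimws(substr(lines[i], eq + 1,
                                                     nchar(lines[i])))))
    if (is.na(val)) stop("line ", i, ": value for '", key,
                         "' is not numeric")
    out[[key]] <- val
  }
  pk <- intersect(names(out), c("k", "omega", "phi_l", "phi_r", "m", "lo",
                                "g"))
  out$params <- do.call(slip_params, out[pk])
  out
}
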