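# Plain-text readers/writers: CSV with `# key = value` comment headers and
# GROMACS-style two-column XVG tables.

.read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    m <- regmatches(line, regexec("^#\\s*([^=]+?)\\s*=\\s*(.+)\\s*$", line))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  meta
}

.write_meta_header <- function(meta, path) {
  lines <- vapply(names(meta), function(k)
    sprintf("# %s = %s", k, format(meta[[k]])), character(1))
  writeLines(lines, path)
}

#' Write a dilatometry curve to CSV
#'
#' Columns `T_K, rho_gcm3, rho_sd` preceded by `# key = value` comment lines
#' carrying replica count, moisture content, units, and — when present — the
#' generator's ground-truth parameters.
#'
#' @param curve a [dilatometry_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dilatometry_csv <- function(curve, path) {
  meta <- list(units_T = "K", units_rho = "g/cm3",
               n_replicas = attr(curve, "n_replicas"),
               moisture_wt_pct = attr(curve, "moisture_wt_pct"))
  gt <- attr(curve, "ground_truth")
  if (!is.null(gt))
    meta <- c(meta, stats::setNames(gt, paste0("truth_", names(gt))))
  .write_meta_header(meta, path)
  suppressWarnings(utils::write.table(
    as.data.frame(curve)[, c("T_K", "rho_gcm3", "rho_sd")],
    path, sep = ",", row.names = FALSE, col.names = TRUE, append = TRUE,
    quote = FALSE))
  invisible(path)
}

#' Read a dilatometry curve from CSV
#'
#' Accepts files written by [write_dilatometry_csv()] or any CSV with
#' columns `T_K, rho_gcm3` (optional `rho_sd`, `n_rep`), `#` comments
#' allowed.
#'
#' @param path CSV file.
#' @return A [dilatometry_curve()]; header metadata in
#'   `attr(, "file_meta")`.
#' @export
read_dilatometry_csv <- function(path) {
  meta <- .read_header_meta(path)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("T_K", "rho_gcm3") %in% names(d)))
    stop("need columns T_K and rho_gcm3")
  curve <- dilatometry_curve(
    T = d$T_K, rho = d$rho_gcm3,
    rho_sd = if ("rho_sd" %in% names(d)) d$rho_sd else rep(NA_real_, nrow(d)),
    n_replicas = if (!is.null(meta$n_replicas)) as.integer(meta$n_replicas)
      else if ("n_rep" %in% names(d)) as.integer(d$n_rep[1]) else 1L,
    moisture_wt_pct = if (!is.null(meta$moisture_wt_pct))
      meta$moisture_wt_pct else NA_real_
  )
  attr(curve, "file_meta") <- meta
  curve
}

#' Read a two-column XVG table
#'
#' GROMACS-style tables: lines starting with `@` or `#` are comments, data
#' lines hold whitespace-separated numbers; the first two columns are kept.
#'
#' @param path XVG file.
#' @return data.frame with columns `x` and `y`.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[@#]", lines) & nzchar(trimws(lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  data.frame(
    x = vapply(fields, function(f) as.numeric(f[1]), numeric(1)),
    y = vapply(fields, function(f) as.numeric(f[2]), numeric(1))
  )
}

#' Write a two-column table as XVG
#' @param x,y numeric vectors.
#' @param path output file.
#' @param title,xlabel,ylabel header strings.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, y, path, title = "", xlabel = "", ylabel = "") {
  header <- c(sprintf("@    title \"%s\"", title),
              sprintf("@    xaxis  label \"%s\"", xlabel),
              sprintf("@    yaxis  label \"%s\"", ylabel))
  writeLines(c(header, sprintf("%.10g %.10g", x, y)), path)
  invisible(path)
}

#' Write a trajectory set to long-format CSV
#'
#' Columns `mol_id, species, t_ns, x_nm, y_nm, z_nm`, with box dimensions and
#' metadata in `# key = value` comment lines.
#'
#' @param traj a `trajectory_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  meta <- list(units_t = "ns", units_xyz = "nm",
               box_x_nm = traj$box[1], box_y_nm = traj$box[2],
               box_z_nm = traj$box[3], species = traj$species,
               temperature_K = traj$temperature,
               moisture_wt_pct = traj$moisture_wt_pct)
  .write_meta_header(meta, path)
  long <- do.call(rbind, lapply(seq_along(traj$positions), function(i) {
    P <- traj$positions[[i]]
    data.frame(mol_id = i, species = traj$species, t_ns = traj$times,
               x_nm = P[, 1], y_nm = P[, 2], z_nm = P[, 3])
  }))
  suppressWarnings(utils::write.table(long, path, sep = ",",
                                      row.names = FALSE, col.names = TRUE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' Read a trajectory set from long-format CSV
#' @param path file written by [write_trajectory_csv()].
#' @return A `trajectory_set`.
#' @export
read_trajectory_csv <- function(path) {
  meta <- .read_header_meta(path)
  d <- utils::read.csv(path, comment.char = "#")
  ids <- unique(d$mol_id)
  times <- sort(unique(d$t_ns))
  positions <- lapply(ids, function(i) {
    di <- d[d$mol_id == i, ]
    di <- di[order(di$t_ns), ]
    if (!isTRUE(all.equal(di$t_ns, times)))
      stop("time grid differs between molecules")
    as.matrix(di[, c("x_nm", "y_nm", "z_nm")])
  })
  out <- list(
    times = times, positions = positions,
    species = if (!is.null(meta$species)) meta$species else d$species[1],
    box = c(meta$box_x_nm, meta$box_y_nm, meta$box_z_nm),
    temperature = if (!is.null(meta$temperature_K)) meta$temperature_K
      else NA_real_,
    moisture_wt_pct = if (!is.null(meta$moisture_wt_pct))
      meta$moisture_wt_pct else NA_real_
  )
  class(out) <- "trajectory_set"
  out
}
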