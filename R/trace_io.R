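# On-disk formats: plain TSV data files plus structured-text sidecars,
# deterministic byte-for-byte, numbers at full precision.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write and read traces
#'
#' A trace is stored as `<path>` (TSV: `time_s`, `signal_nm`, optional
#' `force_pN`) plus a sidecar `<path>.meta` of `key = value` lines
#' carrying the mandatory metadata and the processing history. The
#' roundtrip is lossless: numbers are serialized with 17 significant
#' digits.
#'
#' @param trace A [lid_trace()].
#' @param path File path (conventionally `*.trace.tsv`).
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the [lid_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "lid_trace"))
  d <- as.data.frame(trace)
  cols <- vapply(d, .fmt_num, character(nrow(d)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1)
  lines <- c(paste(colnames(d), collapse = "\t"),
             apply(cols, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  m <- trace$meta
  meta_lines <- vapply(names(m), function(k) {
    v <- m[[k]]
    v <- if (is.numeric(v)) paste(.fmt_num(v), collapse = ";")
         else paste(as.character(v), collapse = ";")
    paste0(k, " = ", v)
  }, character(1))
  writeLines(meta_lines, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(path)) stop("trace file not found: ", path)
  if (!file.exists(meta_path)) stop("sidecar not found: ", meta_path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "numeric")
  if (nrow(d) > 1) {
    bad <- which(diff(d$time_s) <= 0)
    if (length(bad) > 0) {
      stop("time not strictly increasing in ", path, " at line ",
           bad[1] + 2)  # +1 header, +1 next row
    }
  }
  raw <- readLines(meta_path)
  raw <- raw[nzchar(trimws(raw))]
  kv <- regmatches(raw, regexec("^([^=]+?)\\s*=\\s*(.*)$", raw))
  meta <- list()
  for (m in kv) {
    if (length(m) != 3) stop("malformed sidecar line: ", m[1])
    key <- trimws(m[2]); val <- m[3]
    parts <- strsplit(val, ";", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    meta[[key]] <- if (!anyNA(num) && length(num) > 0 &&
                       key != "history" && key != "ligand") num else parts
  }
  numeric_keys <- c("concentration", "trap_k1_pN_per_nm",
                    "trap_k2_pN_per_nm", "trap_separation_nm",
                    "sampling_rate_hz")
  for (k in intersect(numeric_keys, names(meta))) {
    meta[[k]] <- as.numeric(meta[[k]])
  }
  if (is.null(meta$history)) meta$history <- character(0)
  meta$history <- as.character(meta$history)
  lid_trace(d$time_s, d$signal_nm,
            force_pN = if ("force_pN" %in% names(d)) d$force_pN else NULL,
            meta = meta)
}

#' Write and read dwell tables
#'
#' TSV columns: `state`, `t_start_s`, `duration_s`, `mean_force_pN`,
#' `censored`; metadata in a `<path>.meta` sidecar.
#'
#' @param dwells A `dwell_set`.
#' @param path File path (conventionally `*.dwells.tsv`).
#' @return `write_dwells` returns `path` invisibly; `read_dwells` the
#'   `dwell_set`.
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_set"))
  lines <- c("state\tt_start_s\tduration_s\tmean_force_pN\tcensored",
             sprintf("%s\t%s\t%s\t%s\t%d", dwells$state,
                     .fmt_num(dwells$t_start_s),
                     .fmt_num(dwells$duration_s),
                     .fmt_num(dwells$mean_force_pN),
                     as.integer(dwells$censored)))
  writeLines(lines, path)
  m <- attr(dwells, "meta")
  meta_lines <- vapply(names(m), function(k) {
    v <- m[[k]]
    v <- if (is.numeric(v)) paste(.fmt_num(v), collapse = ";")
         else paste(as.character(v), collapse = ";")
    paste0(k, " = ", v)
  }, character(1))
  writeLines(meta_lines, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_dwells
#' @export
read_dwells <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  meta <- list()
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    raw <- readLines(meta_path)
    raw <- raw[nzchar(trimws(raw))]
    kv <- regmatches(raw, regexec("^([^=]+?)\\s*=\\s*(.*)$", raw))
    for (m in kv) {
      key <- trimws(m[2])
      num <- suppressWarnings(as.numeric(m[3]))
      meta[[key]] <- if (!is.na(num) && key != "ligand") num else m[3]
    }
  }
  dwell_set(d$state, d$t_start_s, d$duration_s, d$mean_force_pN,
            as.logical(d$censored), meta = meta)
}

#' Write and read force-distance curves
#'
#' TSV columns `trap_distance_nm`, `force_pN`; velocity and direction in a
#' header comment.
#'
#' @param fec A `lid_fec` object.
#' @param path File path (conventionally `*.fec.tsv`).
#' @return `write_fec` returns `path` invisibly; `read_fec` the `lid_fec`.
#' @export
write_fec <- function(fec, path) {
  stopifnot(inherits(fec, "lid_fec"))
  lines <- c(sprintf("# velocity_nm_s = %s",
                     .fmt_num(attr(fec, "velocity_nm_s"))),
             sprintf("# direction = %s", attr(fec, "direction")),
             "trap_distance_nm\tforce_pN",
             sprintf("%s\t%s", .fmt_num(fec$trap_distance_nm),
                     .fmt_num(fec$force_pN)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fec
#' @export
read_fec <- function(path) {
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  get <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "\\s*="), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  d <- utils::read.table(text = raw[!startsWith(raw, "#")], header = TRUE,
                         sep = "\t")
  structure(d, class = c("lid_fec", "data.frame"),
            velocity_nm_s = as.numeric(get("velocity_nm_s", NA)),
            direction = get("direction", "stretch"))
}

#' Read a 2D free-energy grid file
#'
#' Parses a whitespace-separated three-column file (AMP-lid opening
#' coordinate in Angstrom, ATP-lid opening coordinate in Angstrom, free
#' energy) into a rectangular [pmf_grid()]. The energy unit must be
#' declared in a header comment `# unit: kcal/mol` or `# unit: kBT`;
#' kcal/mol grids are converted to kBT at the configured temperature.
#' Missing cells (omitted umbrella windows) become masked (`NA`) cells.
#'
#' @param path File path (conventionally `*.pmf2d.dat`).
#' @param constants A [lid_constants()] object (for unit conversion).
#' @return A [pmf_grid()] in kBT.
#' @export
read_pmf_grid <- function(path, constants = lid_constants()) {
  raw <- readLines(path)
  hdr <- raw[startsWith(raw, "#")]
  unit_line <- grep("^#\\s*unit\\s*:", hdr, value = TRUE)
  if (length(unit_line) == 0) {
    stop("PMF grid header must declare a unit, e.g. '# unit: kcal/mol'")
  }
  unit <- trimws(sub("^#\\s*unit\\s*:", "", unit_line[1]))
  if (!unit %in% c("kcal/mol", "kBT")) stop("unknown PMF unit: ", unit)
  body <- raw[!startsWith(raw, "#")]
  body <- body[nzchar(trimws(body))]
  d <- utils::read.table(text = body, col.names = c("a", "b", "g"))
  ax_a <- sort(unique(d$a))
  ax_b <- sort(unique(d$b))
  key <- paste(match(d$a, ax_a), match(d$b, ax_b))
  if (anyDuplicated(key)) stop("ragged PMF grid: duplicate coordinates")
  g <- matrix(NA_real_, length(ax_a), length(ax_b))
  g[cbind(match(d$a, ax_a), match(d$b, ax_b))] <- d$g
  if (unit == "kcal/mol") g <- kcal_per_mol_to_kBT(g, constants)
  pmf_grid(ax_a, ax_b, g)
}

#' @rdname read_pmf_grid
#' @param grid A [pmf_grid()] (energies in kBT).
#' @param unit Unit to write, `"kBT"` or `"kcal/mol"`.
#' @export
write_pmf_grid <- function(grid, path, unit = c("kBT", "kcal/mol"),
                           constants = lid_constants()) {
  stopifnot(inherits(grid, "pmf_grid"))
  unit <- match.arg(unit)
  g <- grid$free_energy_kBT
  if (unit == "kcal/mol") g <- kBT_to_kcal_per_mol(g, constants)
  idx <- which(!is.na(g), arr.ind = TRUE)
  lines <- c(paste0("# unit: ", unit),
             sprintf("%s %s %s", .fmt_num(grid$d_AMP_A[idx[, 1]]),
                     .fmt_num(grid$d_ATP_A[idx[, 2]]),
                     .fmt_num(g[idx])))
  writeLines(lines, path)
  invisible(path)
}
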