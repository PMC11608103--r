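#' Read and write forcing files
#'
#' Tab-delimited daily forcing: columns `date` (day index or ISO date),
#' `precip` (mm/day), `temp` (degC), `pet` (mm/day), plus one
#' `chem_<species>` column (mol/L) per precipitation-chemistry species.
#' Readers and writers round-trip bit-stably.
#'
#' @param path File path.
#' @return A forcing tibble; precipitation chemistry columns keep the
#'   `chem_` prefix.
#' @export
read_forcing <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("date", "precip", "temp", "pet")
  if (!all(need %in% names(x)))
    stopf("forcing file lacks columns: %s",
          paste(setdiff(need, names(x)), collapse = ", "))
  if (any(x$precip < 0) || any(x$pet < 0))
    stopf("negative precipitation or PET in %s", path)
  x
}

#' @rdname read_forcing
#' @param forcing Forcing tibble.
#' @export
write_forcing <- function(forcing, path) {
  readr::write_tsv(forcing, path, progress = FALSE)
  invisible(path)
}

# precipitation chemistry (mol/L) matrix from chem_ columns
forcing_chem <- function(forcing) {
  cols <- grep("^chem_", names(forcing), value = TRUE)
  m <- as.matrix(forcing[cols])
  colnames(m) <- sub("^chem_", "", cols)
  m
}

#' Read HBV-light-style results and parameter files
#'
#' Reads the documented tab-delimited dialect of a bucket-model results file
#' (named columns: `date`, `precip`, `temp`, `pet`, `swe`, `sm`, `uz`, `lz`,
#' `aet`, `q_sf`, `q_sz`, `q_dz`) and a key-value parameter file
#' (`<name><TAB><value>` per line, names as in [hbv_params()]). Fluxes the
#' results file does not carry are back-calculated from the storages and
#' parameters so each store's balance closes exactly: snowfall/rain from the
#' temperature threshold, snowmelt from the snow store balance, percolation
#' from the lower-store balance (`q_perc = lz - lag(lz) + q_dz`), and
#' infiltration as `rain + snowmelt - q_sf`.
#'
#' @param results_path,params_path File paths.
#' @param init Named list of initial stores for the back-calculation
#'   (`swe`, `lz`), mm; defaults take day 1 as its own reference.
#' @return A list with `hydro` (an `rt_hydro` tibble) and `params`
#'   ([hbv_params()]).
#' @export
read_hbv_light <- function(results_path, params_path, init = list()) {
  par_lines <- readLines(params_path, warn = FALSE)
  par_lines <- par_lines[!grepl("^\\s*(#|$)", par_lines)]
  kv <- strsplit(par_lines, "\t", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stopf("parameter file %s: expected '<name>\\t<value>' lines", params_path)
  vals <- stats::setNames(as.numeric(vapply(kv, `[[`, "", 2)),
                          vapply(kv, `[[`, "", 1))
  known <- names(formals(hbv_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("parameter file %s: unknown parameter(s) %s",
                         params_path, paste(bad, collapse = ", "))
  params <- do.call(hbv_params, as.list(vals))

  x <- readr::read_tsv(results_path, show_col_types = FALSE, progress = FALSE)
  need <- c("date", "precip", "temp", "pet", "swe", "sm", "uz", "lz", "aet",
            "q_sf", "q_sz", "q_dz")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stopf("results file %s lacks column(s): %s (expected: %s)",
          results_path, paste(missing, collapse = ", "),
          paste(need, collapse = ", "))
  n <- nrow(x)
  if (n < 2) stopf("results file %s is truncated (need >= 2 days)", results_path)
  psnow <- ifelse(x$temp <= params$tt, x$precip, 0)
  rain <- x$precip - psnow
  swe_prev <- c(init$swe %||% x$swe[1] - psnow[1], x$swe[-n])
  melt <- swe_prev + psnow - x$swe
  if (any(melt < -1e-9))
    stopf("results file %s: snow store balance yields negative melt", results_path)
  melt <- pmax(melt, 0)
  # percolation from the lower-store balance; day 1 uses the given initial
  # store, or assumes a steady store when none is given
  lz_prev <- c(init$lz %||% x$lz[1], x$lz[-n])
  qperc <- pmax(x$lz - lz_prev + x$q_dz, 0)
  h <- tibble(date = x$date, precip = x$precip, temp = x$temp, pet = x$pet,
              p_snow = psnow, rain = rain, snowmelt = melt, swe = x$swe,
              sm = x$sm, uz = x$uz, lz = x$lz, aet = x$aet,
              q_sf = x$q_sf, q_sz = x$q_sz, q_dz = x$q_dz,
              q = x$q_sf + x$q_sz + x$q_dz,
              q_infil = pmax(rain + melt - x$q_sf, 0), q_perc = qperc)
  list(hydro = structure(h, class = c("rt_hydro", class(tibble()))),
       params = params)
}

#' Write an HBV-light-style results file and parameter file
#'
#' Inverse of [read_hbv_light()], used to exchange hydrology with external
#' bucket-model runs and to build test fixtures.
#'
#' @param hydro An `rt_hydro` tibble.
#' @param params An [hbv_params()].
#' @param results_path,params_path Output paths.
#' @export
write_hbv_light <- function(hydro, params, results_path, params_path) {
  cols <- c("date", "precip", "temp", "pet", "swe", "sm", "uz", "lz", "aet",
            "q_sf", "q_sz", "q_dz")
  readr::write_tsv(hydro[cols], results_path, progress = FALSE)
  writeLines(sprintf("%s\t%s", names(unclass(params)),
                     fmt_num(unlist(params))), params_path)
  invisible(results_path)
}
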