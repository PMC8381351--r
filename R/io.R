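#' Read a two-column spectrum file
#'
#' Expects delimited text (comma or tab, auto-detected) with a header line
#' `energy_eV,intensity` (any names; the first two columns are used) and
#' numeric rows. A descending grid is re-sorted ascending with a warning.
#'
#' @param path File path.
#' @param pH,region,resolution_fwhm,label Metadata for the resulting
#'   [pes_spectrum()]; not stored in the two-column file itself.
#' @return A [pes_spectrum()].
#' @export
read_spectrum <- function(path, pH = NA_real_, region = "C1s",
                          resolution_fwhm = 0, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty spectrum file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("spectrum file must have two columns (energy, intensity): ", path,
         call. = FALSE)
  }
  e <- suppressWarnings(as.numeric(df[[1L]]))
  y <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(e) | !is.finite(y))
  if (length(bad)) {
    stop("non-numeric spectrum data at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  if (is.unsorted(e) && !is.unsorted(rev(e))) {
    warning("descending energy grid in ", basename(path),
            "; re-sorting ascending")
  } else if (is.unsorted(e)) {
    warning("unsorted energy grid in ", basename(path),
            "; re-sorting ascending")
  }
  ord <- order(e)
  pes_spectrum(e[ord], y[ord], pH = pH, region = region,
               resolution_fwhm = resolution_fwhm, label = label)
}

#' Write a spectrum as two-column CSV
#'
#' @param spectrum A [pes_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a vertical-ionization-energy table
#'
#' Delimited text with columns `species,site,vie_eV`.
#'
#' @param path File path.
#' @return A [vie_table()].
#' @export
read_vie_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "site", "vie_eV")
  if (!all(need %in% names(df))) {
    stop("VIE table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vie_table(df$species, df$site, df$vie_eV)
}

#' Write a synthetic titration series to disk
#'
#' Emits one two-column CSV per spectrum (plus one per O 1s calibration
#' reference) and a YAML manifest recording pH, file names, the
#' generator's ground truth and per-spectrum draws. The manifest doubles
#' as the input of [run_pipeline()].
#'
#' @param generated Output of [make_c1s_series()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem for the per-spectrum CSVs.
#' @return Path of the manifest file, invisibly.
#' @export
write_series <- function(generated, dir, stem = "spectrum") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- generated$manifest
  has_refs <- !is.null(generated$references)
  entries <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fn <- sprintf("%s_pH%04.1f.csv", stem, man$pH[i])
    write_spectrum(generated$series[[i]], file.path(dir, fn))
    entry <- list(file = fn, pH = man$pH[i],
                  true_fraction = man$true_fraction[i],
                  applied_offset_eV = man$applied_offset_eV[i],
                  seed = man$seed[i])
    if (has_refs) {
      rf <- sprintf("%s_pH%04.1f_o1s.csv", stem, man$pH[i])
      write_spectrum(generated$references[[i]], file.path(dir, rf))
      entry$reference <- rf
    }
    entries[[i]] <- entry
  }
  manifest <- list(true_pka = attr(man, "true_pka"), spectra = entries)
  if (has_refs) manifest$reference_center <- generated$reference_center
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Run the full spectro-titration pipeline from a configuration
#'
#' Orchestrates the photoemission-spectroscopy titration end to end: load
#' the series named by the manifest, area-normalize, align, unmix each
#' spectrum against the designated low/high-pH basis curves, fit the
#' rearranged Henderson-Hasselbalch model, and write a machine-readable
#' JSON report embedding the resolved configuration. Reports contain no
#' timestamps, so identical configurations yield byte-identical reports.
#'
#' @param config Either a path to a YAML configuration file or a list with
#'   elements:
#' \describe{
#'   \item{manifest}{path to a series manifest written by [write_series()]
#'     (entries `file`, `pH`, optional `reference`).}
#'   \item{basis_low_ph, basis_high_ph}{pH values designating the basis
#'     spectra (default: lowest and highest pH present).}
#'   \item{reference_center}{binding energy (eV) of the calibration line;
#'     defaults to the manifest's `reference_center` when present. With
#'     reference spectra available, each spectrum is calibrated before
#'     unmixing.}
#'   \item{window, align_window}{optional numeric windows in eV.}
#'   \item{align}{logical, default TRUE (ignored when calibrating).}
#'   \item{out}{optional path for the JSON report.}
#' }
#' @return The report as a list (invisibly written to `config$out` when
#'   set), containing `pka`, `pka_uncertainty`, per-pH ratios, flags and
#'   the resolved configuration.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$manifest)) {
    stop("configuration error: missing required key `manifest`",
         call. = FALSE)
  }
  if (!file.exists(config$manifest)) {
    stop("configuration error: manifest not found: ", config$manifest,
         call. = FALSE)
  }
  man <- yaml::read_yaml(config$manifest)
  base_dir <- dirname(config$manifest)
  if (!length(man$spectra)) {
    stop("manifest lists no spectra", call. = FALSE)
  }
  resolve <- function(f) {
    fp <- if (file.exists(f)) f else file.path(base_dir, f)
    if (!file.exists(fp)) {
      stop("configuration error: missing spectrum file `", f, "`",
           call. = FALSE)
    }
    fp
  }
  series <- lapply(man$spectra, function(e) {
    read_spectrum(resolve(e$file), pH = e$pH)
  })
  ph <- vapply(series, function(s) s$meta$pH, numeric(1))

  references <- NULL
  reference_center <- config$reference_center
  if (is.null(reference_center)) reference_center <- man$reference_center
  if (!is.null(reference_center) &&
      all(vapply(man$spectra, function(e) !is.null(e$reference),
                 logical(1)))) {
    references <- lapply(man$spectra, function(e) {
      read_spectrum(resolve(e$reference), pH = e$pH, region = "O1s")
    })
  }

  pick_basis <- function(key, default_ph) {
    want <- if (!is.null(config[[key]])) as.numeric(config[[key]]) else
      default_ph
    if (!any(abs(ph - want) < 1e-9)) {
      stop("configuration error: no spectrum at `", key, "` = ", want,
           call. = FALSE)
    }
    want
  }
  basis_low <- pick_basis("basis_low_ph", min(ph))
  basis_high <- pick_basis("basis_high_ph", max(ph))

  res <- run_titration(series, basis_low = basis_low, basis_high = basis_high,
                       references = references,
                       reference_center = reference_center,
                       window = config$window,
                       align_window = if (is.null(config$align_window)) 1.0
                                      else config$align_window,
                       align = !isFALSE(config$align))

  report <- list(
    pipeline = "photoemission spectroscopy titration",
    pka = res$pka,
    pka_uncertainty = res$pka_uncertainty,
    points = res$points,
    flags = list(extrapolation = res$extrapolation,
                 pka2_deviation = res$pka2_flag),
    config = config)
  if (!is.null(config$out)) {
    jsonlite::write_json(report, config$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  }
  report
}
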