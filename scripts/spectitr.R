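#!/usr/bin/env Rscript
# Thin command-line front end over the spectitr package.
#
#   Rscript scripts/spectitr.R simulate --out <dir> [--seed N] [--pka X]
#                                       [--snr X] [--noiseless]
#   Rscript scripts/spectitr.R titrate --manifest <file> [--out <report.json>]
#                                      [--basis-low pH] [--basis-high pH]
#   Rscript scripts/spectitr.R fit-peaks --spectrum <csv> --window lo,hi
#                                        [--centers c1,c2] [--ratio r]
#   Rscript scripts/spectitr.R pka-thermo --energies <csv> [--temperature K]
#       (columns: site,dg_gas,dgsolv_reactants,dgsolv_products; kcal/mol)
#   Rscript scripts/spectitr.R convert-energy --value X --from U --to U
#       (units: kJ/mol, kcal/mol, eV, Hartree)

suppressPackageStartupMessages(library(spectitr))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) {
  stop("usage: spectitr.R <simulate|titrate|fit-peaks|pka-thermo|",
       "convert-energy> [options]", call. = FALSE)
}
cmd <- argv[1]
args <- argv[-1]

get_opt <- function(name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for --", name, call. = FALSE)
  args[i[1] + 1L]
}
has_flag <- function(name) any(args == paste0("--", name))
num_opt <- function(name, default = NULL) {
  v <- get_opt(name)
  if (is.null(v)) default else as.numeric(v)
}

status <- 0L
tryCatch({
  if (cmd == "simulate") {
    out_dir <- get_opt("out")
    if (is.null(out_dir)) stop("simulate requires --out <dir>")
    cfg <- synthetic_config(
      true_pka = num_opt("pka", 12.18),
      snr = if (has_flag("noiseless")) Inf else num_opt("snr", 50),
      charging_offset_sd = if (has_flag("noiseless")) 0 else
        num_opt("offset-sd", 0.1),
      seed = as.integer(num_opt("seed", 1)))
    manifest <- write_series(make_c1s_series(cfg), out_dir)
    cat("manifest:", manifest, "\n")
  } else if (cmd == "titrate") {
    manifest <- get_opt("manifest")
    if (is.null(manifest)) stop("titrate requires --manifest <file>")
    cfg <- list(manifest = manifest, out = get_opt("out"),
                basis_low_ph = num_opt("basis-low"),
                basis_high_ph = num_opt("basis-high"))
    report <- run_pipeline(cfg[!vapply(cfg, is.null, logical(1))])
    cat(sprintf("pKa = %.4f +/- %.4f\n", report$pka,
                report$pka_uncertainty))
  } else if (cmd == "fit-peaks") {
    path <- get_opt("spectrum")
    if (is.null(path)) stop("fit-peaks requires --spectrum <csv>")
    window <- as.numeric(strsplit(get_opt("window"), ",")[[1]])
    centers <- as.numeric(strsplit(
      get_opt("centers", paste(mean(window) + c(1, -1) * diff(window) / 6,
                               collapse = ",")), ",")[[1]])
    ratio <- num_opt("ratio")
    comps <- lapply(centers, function(c0) gaussian_component(c0, 0.5, 1))
    cons <- if (!is.null(ratio) && length(centers) == 2L) {
      list(area_ratio(1, 2, ratio))
    } else list()
    fit <- fit_peak_model(read_spectrum(path), peak_model(comps, cons),
                          fit_window = window)
    print(fit)
  } else if (cmd == "pka-thermo") {
    path <- get_opt("energies")
    if (is.null(path)) stop("pka-thermo requires --energies <csv>")
    pk <- pka_thermo_cycle(utils::read.csv(path),
                           temperature = num_opt("temperature", 298.15))
    rk <- rank_sites(pk)
    for (s in rk$order) cat(sprintf("%-8s pKa %.2f\n", s, rk$pkas[[s]]))
    cat(sprintf("most acidic: %s (gap to next: %.2f)\n", rk$order[1],
                rk$first_gap))
  } else if (cmd == "convert-energy") {
    v <- convert_energy(num_opt("value"), get_opt("from"), get_opt("to"))
    cat(v, "\n")
  } else {
    stop("unknown subcommand: ", cmd)
  }
}, error = function(e) {
  message("error: ", conditionMessage(e))
  status <<- 1L
})
quit(status = status)
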