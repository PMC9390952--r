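# Plain-text interchange: per-subject matrices as TSV plus a JSON manifest.

#' Write a simulated study to a directory
#'
#' One tab-separated file per subject (`subject_XX.tsv`, time in rows),
#' the true group/individual maps, the mixing matrices, and a
#' `manifest.json` recording the design and seed, so a run can be redone
#' or evaluated elsewhere.
#'
#' @param sim A `"simulation_truth"` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "simulation_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f)
    utils::write.table(m, file.path(dir, f), sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  for (i in seq_along(sim$data)) {
    wr(sim$data[[i]], sprintf("subject_%02d.tsv", i))
    wr(sim$individual_maps[[i]], sprintf("individual_maps_%02d.tsv", i))
    wr(sim$mixing[[i]], sprintf("mixing_%02d.tsv", i))
  }
  wr(sim$group_maps, "group_maps.tsv")
  d <- sim$design
  manifest <- list(
    n_subjects = d$n_subjects, grid = d$grid, q_g = d$q_g, q_I = d$q_I,
    n_gauss = d$n_gauss, T = d$T, V = d$V, svar_setting = d$svar_setting,
    phi = d$phi, fwhm = d$fwhm, gamma_shape = d$gamma_shape,
    gamma_rate = d$gamma_rate, seed = d$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing `manifest.json` and the TSV matrices.
#' @return A list with `design` (reconstructed [simulation_design()]),
#'   `data`, `group_maps`, `individual_maps`, `mixing`.
#' @export
read_study <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  design <- simulation_design(
    n_subjects = man$n_subjects, grid = man$grid, q_g = man$q_g,
    q_I = man$q_I, n_gauss = man$n_gauss, svar_setting = man$svar_setting,
    phi = man$phi, fwhm = man$fwhm, gamma_shape = man$gamma_shape,
    gamma_rate = man$gamma_rate, seed = man$seed)
  rd <- function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  k <- man$n_subjects
  list(design = design,
       data = lapply(seq_len(k), function(i)
         unname(rd(sprintf("subject_%02d.tsv", i)))),
       group_maps = unname(rd("group_maps.tsv")),
       individual_maps = lapply(seq_len(k), function(i)
         unname(rd(sprintf("individual_maps_%02d.tsv", i)))),
       mixing = lapply(seq_len(k), function(i)
         unname(rd(sprintf("mixing_%02d.tsv", i)))))
}
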