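#' Default run configuration
#'
#' Resolved configuration shared by the pipeline entry points. Every run
#' writes its resolved configuration next to its outputs, so reports are
#' reproducible byte-for-byte given identical inputs and config.
#'
#' @param ... Overrides of the defaults (unknown keys are an error).
#' @return Named list: `window`, `allow_conditional`, `fp_model`,
#'   `sasa_probe`, `sasa_points`, `hbond_dmax`, `hbond_angle_min`,
#'   `salt_dmax`, `pocket_dmax`, `seed`.
#' @export
default_config <- function(...) {
  cfg <- list(
    window = 4L, allow_conditional = FALSE, fp_model = "depletion",
    sasa_probe = 1.4, sasa_points = 960L,
    hbond_dmax = 3.5, hbond_angle_min = 120,
    salt_dmax = 4.0, pocket_dmax = 4.5, seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste("Unknown config key(s):", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file of key-value overrides.
#' @return A resolved config list (see [default_config()]).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Run the motif-scan pipeline over a FASTA file
#'
#' Scans every record for FIR cores (phospho-aware when an annotation
#' table is supplied), classifies modes, and writes a TSV report with a
#' frozen column order plus a JSON summary (match counts per mode and
#' the resolved configuration).
#'
#' @param fasta FASTA path or named sequences (see [scan_fasta()]).
#' @param phospho Optional phospho TSV path or data frame.
#' @param out_dir Output directory; created if missing. When `NULL`,
#'   nothing is written.
#' @param config Resolved config list from [default_config()].
#' @param offsets Optional named offsets per record.
#' @return The report tibble, invisibly when `out_dir` is given.
#' @export
run_scan_pipeline <- function(fasta, phospho = NULL, out_dir = NULL,
                              config = default_config(), offsets = NULL) {
  report <- scan_fasta(fasta, phospho = phospho, offsets = offsets,
                       allow_conditional = config$allow_conditional,
                       window = config$window)
  report <- arrange(report, match(.data$id, unique(.data$id)), .data$psi_pos)
  if (is.null(out_dir)) return(report)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report, file.path(out_dir, "fir_scan.tsv"))
  summary <- list(
    n_records = length(unique(report$id)),
    n_matches = nrow(report),
    matches_per_mode = as.list(table(report$mode)),
    config = config)
  jsonlite::write_json(summary, file.path(out_dir, "fir_scan_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Run the full structure interface report
#'
#' Orchestrates the interface characterization for one complex: buried
#' surface area (both conventions), hydrogen bonds with a
#' backbone-backbone tally, salt bridges, and LHP/SHG pocket contacts
#' for the peptide group.
#'
#' @param model A `structure_model` or PDB path.
#' @param groupA,groupB Selections (typically Claw chain vs peptide
#'   chain); `groupB` is treated as the peptide for pocket contacts.
#' @param config Resolved config list.
#' @param out_dir Optional output directory for JSON + TSV reports.
#' @return An `interface_report` list: `bsa`, `hbonds`,
#'   `n_backbone_hbonds`, `salt_bridges`, `pocket_contacts`, `config`.
#' @export
run_structure_report <- function(model, groupA, groupB,
                                 config = default_config(), out_dir = NULL) {
  if (is.character(model)) model <- read_structure(model)
  bsa <- buried_surface(model, groupA, groupB,
                        probe = config$sasa_probe,
                        n_points = config$sasa_points)
  hb <- hydrogen_bonds(model, groupA, groupB,
                       d_max = config$hbond_dmax,
                       angle_min = config$hbond_angle_min)
  sb <- salt_bridges(model, groupA, groupB, d_max = config$salt_dmax)
  pc <- pocket_contacts(model, groupB, d_max = config$pocket_dmax)
  report <- structure(list(
    bsa = bsa, hbonds = hb,
    n_backbone_hbonds = sum(hb$class == "backbone-backbone"),
    salt_bridges = sb, pocket_contacts = pc, config = config),
    class = "interface_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(hb, file.path(out_dir, "hbonds.tsv"))
    readr::write_tsv(sb, file.path(out_dir, "salt_bridges.tsv"))
    readr::write_tsv(pc, file.path(out_dir, "pocket_contacts.tsv"))
    readr::write_tsv(bsa$per_residue, file.path(out_dir, "buried_per_residue.tsv"))
    jsonlite::write_json(list(
      bsa_sum = bsa$bsa_sum, bsa_half = bsa$bsa_half,
      n_hbonds = nrow(hb), n_backbone_hbonds = report$n_backbone_hbonds,
      n_salt_bridges = nrow(sb), config = config),
      file.path(out_dir, "interface_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report>\n")
  cat(sprintf("  buried area: sum %.1f A^2 (half %.1f)\n",
              x$bsa$bsa_sum, x$bsa$bsa_half))
  cat(sprintf("  hydrogen bonds: %d (%d backbone-backbone)\n",
              nrow(x$hbonds), x$n_backbone_hbonds))
  cat(sprintf("  salt bridges: %d; pocket contacts: %d\n",
              nrow(x$salt_bridges), nrow(x$pocket_contacts)))
  invisible(x)
}

#' Plot scanned motif hits along a set of records
#'
#' @param report Tibble from [scan_fasta()] / [run_scan_pipeline()].
#' @return A ggplot: hit positions by record, colored by mode.
#' @export
plot_fir_matches <- function(report) {
  stopifnot(is.data.frame(report))
  ggplot2::ggplot(report,
    ggplot2::aes(x = .data$protein_pos, y = .data$id, color = .data$mode)) +
    ggplot2::geom_point(size = 3, shape = 17) +
    ggplot2::labs(x = "protein coordinate of psi", y = NULL, color = "mode") +
    ggplot2::theme_minimal()
}

#' Plot an annotated fragment spectrum
#'
#' @param matched Result of [match_peaks()].
#' @param peaks The peak list that was annotated.
#' @return A ggplot of the spectrum with matched ions labeled.
#' @export
plot_spectrum <- function(matched, peaks) {
  ann <- filter(matched$annotations, !is.na(.data$obs_mz))
  ggplot2::ggplot(as_tibble(peaks), ggplot2::aes(x = .data$mz)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, y = 0,
                                       yend = .data$intensity), color = "grey60") +
    ggplot2::geom_segment(data = ann,
      ggplot2::aes(x = .data$obs_mz, xend = .data$obs_mz, y = 0,
                   yend = .data$intensity), color = "firebrick") +
    ggplot2::geom_text(data = ann,
      ggplot2::aes(x = .data$obs_mz, y = .data$intensity,
                   label = paste0(.data$series, .data$index)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}
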