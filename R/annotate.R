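# End-to-end annotation pipeline: SASA -> cavities -> nests -> template
# matching -> conservation -> evidence integration, with JSON/TSV/PDB
# outputs.  This is the programmatic surface behind the command-line
# script shipped in inst/scripts/funsite.R.

#' Run the full functional-site annotation pipeline
#'
#' Runs solvent accessibility, cavity detection, nest detection, template
#' matching (when a template is given) and conservation mapping (when an
#' alignment is given) on one structure, and integrates the evidence into a
#' ranked site report.  When `out_dir` is given, writes `report.json`, a
#' per-residue `residues.tsv` (SASA, conservation, evidence membership) and
#' a conservation-coloured PDB (scores scaled to 0-99.99 in the B-factor
#' column).
#'
#' @param pdb path to a PDB file or a `structure3d`
#' @param chain chain to analyse (default: first chain)
#' @param msa optional alignment path or `aa_alignment`
#' @param msa_row alignment row corresponding to the structure (default:
#'   first row)
#' @param template optional template JSON path or `site_template`
#' @param spacing,probe cavity-grid parameters (see [detect_cavities()])
#' @param rmsd_cutoff template-match cutoff (see [match_template()])
#' @param exposure_min relative-SASA surface threshold
#' @param weights evidence weights (see [integrate_evidence()])
#' @param out_dir optional output directory
#' @return a `site_report` (with attribute `"outputs"` listing files
#'   written, when `out_dir` is given)
#' @export
annotate_structure <- function(pdb, chain = NULL, msa = NULL, msa_row = NULL,
                               template = NULL, spacing = 0.9, probe = 1.4,
                               rmsd_cutoff = 2.5, exposure_min = 0.2,
                               weights = c(1, 1, 2, 0.5, 0.5),
                               out_dir = NULL) {
  st <- if (inherits(pdb, "structure3d")) pdb else read_structure(pdb)
  if (is.null(chain)) chain <- st$atoms$chain[1]

  sasa <- shrake_rupley_sasa(st, probe = probe)
  cavities <- detect_cavities(st, spacing = spacing, probe = probe)
  nests <- detect_nests(st, chain)
  aromatics <- exposed_aromatics(st, sasa, threshold = exposure_min)

  hits <- NULL
  if (!is.null(template)) {
    tpl <- if (inherits(template, "site_template")) template
           else read_template(template)
    hits <- match_template(st, tpl, rmsd_cutoff = rmsd_cutoff)
  }
  profile <- NULL
  if (!is.null(msa)) {
    aln <- if (inherits(msa, "aa_alignment")) msa else read_msa(msa)
    if (is.null(msa_row)) msa_row <- rownames(aln$mat)[1]
    profile <- map_to_structure(aln, msa_row, st, chain)
  }
  report <- integrate_evidence(st, cavities, profile = profile, hits = hits,
                               nests = nests, aromatics = aromatics,
                               weights = weights, rmsd_cutoff = rmsd_cutoff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(report = file.path(out_dir, "report.json"),
               residues = file.path(out_dir, "residues.tsv"),
               pdb = file.path(out_dir, "conservation.pdb"))
    jsonlite::write_json(site_report_json(report), files["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res <- sasa$residue
    res$conservation <- if (is.null(profile)) NA_real_ else
      profile$residue_scores$score[match(res$key, profile$residue_scores$key)]
    utils::write.table(res, files["residues"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    bf <- NULL
    if (!is.null(profile)) {
      bf <- round(99.99 * profile$residue_scores$score, 2)
      names(bf) <- profile$residue_scores$key
    }
    write_structure(st, files["pdb"], bfactor_override = bf)
    attr(report, "outputs") <- files
  }
  report
}

# JSON-serialisable view of a site report
site_report_json <- function(report) {
  list(weights = report$weights,
       sites = lapply(report$sites, function(s)
         list(rank = s$rank, composite = s$composite, terms = s$terms,
              volume = s$cavity$volume, grid_points = s$cavity$grid_points,
              centroid = s$cavity$centroid,
              lining_residues = s$cavity$lining_residues,
              template_hit = if (is.null(s$template_hit)) NULL else
                list(residues = s$template_hit$residues,
                     rmsd = s$template_hit$rmsd),
              nest_residues = s$nest_residues,
              n_exposed_aromatics = s$n_exposed_aromatics)))
}
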