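#' Run the full analysis workflow from a parsed configuration
#'
#' Preprocesses the trajectory (read, align, optional coordinate-matrix
#' output), then for every configured subset and statistical model performs
#' PCA and writes eigenvalue tables, top eigenvectors, per-mode MSF and PC
#' projections into its own output subdirectory
#' (`<out_dir>/<subset>/<model>/`), so independent analyses never share
#' mutable outputs. Optional stages: RES/ACS shrinkage, hierarchical PCA
#' (with an automatic subspace comparison against the direct decomposition),
#' sparsification of `R`/`P`, residue-pair coupling, kernel PCA and a
#' free-energy surface. A failing analysis is recorded in `errors.log` of
#' its directory; the other analyses continue.
#'
#' @param cfg a `run_config` from [parse_config()], or a path to a parameter
#'   file.
#' @return invisibly, a list describing the analyses run (paths and any
#'   per-analysis error messages).
#' @export
run_workflow <- function(cfg) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  if (!inherits(cfg, "run_config")) stop("expected a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ens <- read_pdb_frames(cfg$input_dir, cfg$reference)
  ens <- quaternion_align(ens)
  if (isTRUE(cfg$do_output_coordinates)) {
    write_coordinate_matrix(ens, file.path(cfg$out_dir,
                                           "aligned_coordinates.txt"))
  }
  mom <- variable_moments(ens)
  write_moment_table(mom, file.path(cfg$out_dir, "variable_moments.tsv"))
  rr <- rmsd_rmsf(ens)
  utils::write.table(
    data.frame(frame = names(rr$rmsd), rmsd = rr$rmsd),
    file.path(cfg$out_dir, "frame_rmsd.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list()
  for (subset_name in cfg$subsets) {
    sub <- select_subset(ens, subset_spec(subset_name,
                                          residue_numbers = cfg$residue_numbers))
    dat <- sub
    if (isTRUE(cfg$res_shrink)) {
      dat <- res_shrink(dat, cfg$res_threshold, cfg$res_center)
    }
    Q <- sample_covariance(dat)
    if (isTRUE(cfg$acs_shrink)) Q <- acs_shrink(Q, centered_data(dat))
    Qc <- condition_floor(Q, cfg$floor)

    model_objs <- list(Q = Qc)
    if ("R" %in% cfg$models) model_objs$R <- correlation_from_cov(Qc)
    if ("P" %in% cfg$models) model_objs$P <- partial_correlation(Qc)

    mode_sets <- list()
    for (model_name in names(model_objs)) {
      adir <- file.path(cfg$out_dir, subset_name, model_name)
      res <- tryCatch({
        run_model_analysis(dat, model_objs[[model_name]], adir, cfg)
      }, error = function(e) {
        dir.create(adir, showWarnings = FALSE, recursive = TRUE)
        writeLines(conditionMessage(e), file.path(adir, "errors.log"))
        list(error = conditionMessage(e))
      })
      if (is.null(res$error)) mode_sets[[model_name]] <- res$modes
      results[[paste(subset_name, model_name, sep = "/")]] <-
        c(list(dir = adir), res["error"])
    }

    # sparsified R/P analyses with automatic comparison to the unaltered model
    if (!is.na(cfg$sparsify_threshold)) {
      for (model_name in intersect(c("R", "P"), names(model_objs))) {
        sp <- sparsify(model_objs[[model_name]], cfg$sparsify_threshold)
        adir <- file.path(cfg$out_dir, subset_name,
                          paste0(model_name, "_sparse"))
        res <- tryCatch(run_model_analysis(dat, sp, adir, cfg),
                        error = function(e) list(error = conditionMessage(e)))
        if (is.null(res$error) && !is.null(mode_sets[[model_name]])) {
          rep <- subspace_report(res$modes, mode_sets[[model_name]],
                                 max_k = cfg$top_k, seed = 1L)
          write_subspace_report(rep, file.path(adir, "ssa_vs_unsparsified.tsv"))
        }
      }
      if (all(c("R", "P") %in% names(model_objs))) {
        asmap <- activator_suppressor_map(model_objs$P, model_objs$R,
                                          cfg$sparsify_threshold)
        utils::write.table(asmap,
                           file.path(cfg$out_dir, subset_name,
                                     "activator_suppressor_map.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }

    if (isTRUE(cfg$hierarchical)) {
      adir <- file.path(cfg$out_dir, subset_name, "HPCA")
      res <- tryCatch({
        ers <- compute_eigenresidues(dat, h = cfg$hierarchical_h)
        hmodes <- hpca(ers, top_k = cfg$top_k)
        write_mode_set(hmodes, adir, top_k = cfg$top_k)
        if (!is.null(mode_sets$Q)) {
          rep <- subspace_report(hmodes, mode_sets$Q, max_k = cfg$top_k,
                                 seed = 1L)
          write_subspace_report(rep, file.path(adir, "ssa_vs_direct.tsv"))
        }
        list(modes = hmodes)
      }, error = function(e) {
        dir.create(adir, showWarnings = FALSE, recursive = TRUE)
        writeLines(conditionMessage(e), file.path(adir, "errors.log"))
        list(error = conditionMessage(e))
      })
      results[[paste(subset_name, "HPCA", sep = "/")]] <-
        c(list(dir = adir), res["error"])
    }

    if (isTRUE(cfg$coupling)) {
      resnums <- cfg$residue_numbers
      if (is.null(resnums)) resnums <- unique(dat$atoms$residue_number)
      if (length(resnums) >= 2L) {
        cm <- coupling_map(dat, resnums, h = cfg$coupling_h,
                           sigma = cfg$sigma)
        write_coupling_map(cm, file.path(cfg$out_dir, subset_name,
                                         "coupling_map.tsv"))
      }
    }
  }
  invisible(results)
}

# One statistical model: decompose, write tables, projections, MSF, optional
# kernel PCA and free-energy surface.
run_model_analysis <- function(dat, model, adir, cfg) {
  dir.create(adir, showWarnings = FALSE, recursive = TRUE)
  modes <- spectral_decompose(model, top_k = cfg$top_k)
  write_mode_set(modes, adir, top_k = cfg$top_k)
  if (!is.na(cfg$sparsify_threshold) || isTRUE(cfg$verbose)) {
    write_stat_model(model, file.path(adir, "model_matrix.txt"))
  }
  pt <- project(dat, modes, "ensemble_mean", top_k = cfg$top_k)
  write_projection_table(pt, file.path(adir, "pc_projections.tsv"))
  msf <- mode_msf(modes, n_atoms(dat), top_k = cfg$top_k)
  utils::write.table(
    data.frame(atom = seq_len(n_atoms(dat)), msf$per_mode,
               combined = msf$combined, check.names = FALSE),
    file.path(adir, "mode_msf.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.na(cfg$kernel)) {
    kp <- kernel_pca(t(pt$proj), kernel_spec(cfg$kernel),
                     top_k = min(2L, cfg$top_k))
    utils::write.table(kp$projections, file.path(adir, "kpca_projections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(cfg$fes) && ncol(pt$proj) >= 2L) {
    fes <- free_energy_surface(pt, grid_size = cfg$grid_size,
                               smoothing = cfg$fes_smoothing)
    write_energy_surface(fes, file.path(adir, "free_energy_surface.tsv"))
  }
  list(modes = modes)
}
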