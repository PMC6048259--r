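#' Add a crystallization-clamp to a toy system
#'
#' Models a stabilizing crystallization agent (a nanobody-like body) as weak
#' harmonic positional restraints on the interface side-chain beads of both
#' chains, anchored at the reference coordinates. The restraint energy is
#' zero at the reference configuration, and a zero-stiffness clamp leaves
#' the dynamics unchanged.
#'
#' @param system a `toy_system` from [build_toy_dimer()]
#' @param k restraint stiffness (kcal/mol/A^2)
#' @return the clamped system
#' @export
apply_clamp <- function(system, k = 1.0) {
  if (is.null(system$interface)) stop("system has no interface annotation")
  beads <- c(system$interface$rec_S, system$interface$lig_S)
  add <- data.frame(bead = beads, k = k,
                    x = system$pos[beads, 1], y = system$pos[beads, 2],
                    z = system$pos[beads, 3])
  system$restraints <- rbind(system$restraints, add)
  system$clamped <- TRUE
  system
}

#' Distance collective variable between the two chain centres of a dimer
#'
#' @param system a `toy_system`
#' @return a [collective_variable()] of kind `"distance"` whose anchor
#'   groups split each chain's backbone beads in two
#' @export
dimer_cv1 <- function(system) {
  rec <- chain_beads(system, "A"); lig <- chain_beads(system, "B")
  half <- function(v) list(a = v[seq_len(ceiling(length(v) / 2))],
                           b = v[-seq_len(ceiling(length(v) / 2))])
  hr <- half(rec); hl <- half(lig)
  if (!length(hr$b)) { hr$b <- hr$a[length(hr$a)]; hr$a <- hr$a[-length(hr$a)] }
  if (!length(hl$b)) { hl$b <- hl$a[length(hl$a)]; hl$a <- hl$a[-length(hl$a)] }
  collective_variable("distance", T = hr$a, U = hr$b, W = hl$a, X = hl$b)
}

#' Plan a comparative toy experiment
#'
#' Mirrors the four-system comparative design (wild type and mutant, each
#' free or clamped, three replicates each) at toy scale.
#'
#' @param variants data frame with columns `variant` (`"WT"`/`"MUT"`) and
#'   `clamped` (logical); defaults to all four combinations
#' @param seeds distinct replicate seeds (default 3 replicates)
#' @param n_receptor_res,n_ligand_res system size
#' @param cmd_steps unbiased production steps per replicate
#' @param abmd_steps adaptive-bias steps per replicate (free variants)
#' @param save_stride frame saving stride
#' @param temperature K
#' @param clamp_k clamp stiffness (kcal/mol/A^2)
#' @param endstate_stride frame subsampling for end-state energetics
#' @param tau flooding timescale (ps)
#' @param output_dir optional directory for TSV outputs
#' @export
experiment_plan <- function(variants = NULL, seeds = c(101L, 202L, 303L),
                            n_receptor_res = 5L, n_ligand_res = 4L,
                            cmd_steps = 20000L, abmd_steps = 400000L,
                            save_stride = 20L, temperature = 310,
                            clamp_k = 1.0, endstate_stride = 5L,
                            tau = 5, output_dir = NULL) {
  if (is.null(variants))
    variants <- expand.grid(variant = c("WT", "MUT"),
                            clamped = c(FALSE, TRUE),
                            stringsAsFactors = FALSE)
  stopifnot(nrow(variants) >= 1, !anyDuplicated(seeds))
  structure(list(variants = variants, seeds = as.integer(seeds),
                 n_receptor_res = n_receptor_res, n_ligand_res = n_ligand_res,
                 cmd_steps = as.integer(cmd_steps),
                 abmd_steps = as.integer(abmd_steps),
                 save_stride = as.integer(save_stride),
                 temperature = temperature, clamp_k = clamp_k,
                 endstate_stride = as.integer(endstate_stride),
                 tau = tau, output_dir = output_dir),
            class = "experiment_plan")
}

variant_label <- function(variant, clamped) {
  paste0(variant, if (clamped) "_clamped" else "_free")
}

#' Run a comparative toy experiment
#'
#' Per variant and replicate: build the system, run unbiased dynamics,
#' compute end-state energetics and interaction fingerprints; for the free
#' variants, additionally run adaptive-bias sampling along the chain-chain
#' distance and extract the binding free energy from the converged bias.
#' Cross-variant: binding results by both routes (with replicate-spread
#' uncertainties), contact-difference maps for the free and clamped
#' conditions, the mutant/wild-type hydrogen-bond ratio table across the
#' four systems, and an attenuation summary comparing difference-map norms.
#' A stage failure is caught and recorded in the bundle's failure manifest.
#'
#' @param plan an [experiment_plan()]
#' @return a `report_bundle` list
#' @export
run_experiment <- function(plan) {
  bundle <- list(plan = plan, per_variant = list(), failures = list())
  vlabels <- mapply(variant_label, plan$variants$variant,
                    plan$variants$clamped)
  for (v in seq_len(nrow(plan$variants))) {
    variant <- plan$variants$variant[v]
    clamped <- plan$variants$clamped[v]
    lab <- vlabels[v]
    pv <- list(variant = variant, clamped = clamped,
               dg_endstate = numeric(), dg_abmd = numeric(),
               maps = list(), hb_counts = list(), hb_frame_totals = list(),
               rmsf = list(), abmd_converged = logical())
    for (s in plan$seeds) {
      stage <- sprintf("%s/seed%d", lab, s)
      res <- tryCatch({
        sys <- build_toy_dimer(plan$n_receptor_res, plan$n_ligand_res,
                               variant, seed = s)
        if (clamped) sys <- apply_clamp(sys, plan$clamp_k)
        cfg <- integrator_config(plan$cmd_steps, save_stride = plan$save_stride,
                                 temperature = plan$temperature, seed = s)
        traj <- discard_equilibration(run_cmd(sys, cfg))
        sub <- subsample(seq_len(n_frames(traj)), plan$endstate_stride)
        traj_sub <- trajectory_ensemble(
          traj$coords[sub, , , drop = FALSE], traj$potential[sub],
          traj$boost[sub], traj$timestep, traj$temperature, traj$seed,
          traj$provenance)
        decomp <- binding_dg_frames(traj_sub, sys,
                                    config = endstate_config(temperature = plan$temperature))
        cm <- contact_map(traj, sys)
        hb <- hbond_pair_counts(traj, sys)
        hbt <- hbond_counts_frames(traj, sys)
        rf <- rmsf(traj, sys)
        dg_ab <- NA_real_; conv <- NA
        if (!clamped) {
          psys <- pmf_restraints(sys)
          cv1 <- dimer_cv1(psys)
          r0 <- eval_cv(psys$pos, cv1, psys$mass)
          lo <- max(2, r0 - 3); hi <- r0 + 15
          acfg <- integrator_config(plan$abmd_steps,
                                    save_stride = plan$save_stride,
                                    temperature = plan$temperature, seed = s)
          ab <- run_abmd(psys, cv1, acfg, lo = lo, hi = hi, ncells = 80L,
                         tau = plan$tau)
          dg_ab <- binding_dg_windows(ab$bias, c(lo, r0 + 3), c(r0 + 8, hi),
                                      plan$temperature)$dg
          conv <- ab$bias$converged
        }
        list(decomp = decomp, cm = cm, hb = hb, hbt = hbt, rf = rf,
             dg_ab = dg_ab, conv = conv)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        bundle$failures[[stage]] <- conditionMessage(res)
        next
      }
      pv$dg_endstate <- c(pv$dg_endstate, res$decomp$dG_binding)
      pv$dg_abmd <- c(pv$dg_abmd, res$dg_ab)
      pv$maps[[length(pv$maps) + 1L]] <- res$cm
      pv$hb_counts[[length(pv$hb_counts) + 1L]] <- res$hb
      pv$hb_frame_totals[[length(pv$hb_frame_totals) + 1L]] <- res$hbt
      pv$rmsf[[length(pv$rmsf) + 1L]] <- res$rf
      pv$abmd_converged <- c(pv$abmd_converged, res$conv)
    }
    bundle$per_variant[[lab]] <- pv
  }

  have <- function(lab) !is.null(bundle$per_variant[[lab]]) &&
    length(bundle$per_variant[[lab]]$dg_endstate) > 0
  mean_map <- function(lab) {
    maps <- bundle$per_variant[[lab]]$maps
    m <- Reduce(`+`, lapply(maps, `[[`, "freq")) / length(maps)
    m
  }
  sum_counts <- function(lab) {
    dfs <- bundle$per_variant[[lab]]$hb_counts
    all <- do.call(rbind, dfs)
    if (is.null(all) || !nrow(all)) return(stats::setNames(numeric(), character()))
    tapply(all$count, all$pair, sum)
  }

  if (have("WT_free") && have("MUT_free")) {
    wt <- bundle$per_variant[["WT_free"]]; mu <- bundle$per_variant[["MUT_free"]]
    bundle$binding_endstate <- binding_result(wt$dg_endstate, mu$dg_endstate,
                                              plan$temperature, "MMPBSA")
    if (all(!is.na(wt$dg_abmd)) && all(!is.na(mu$dg_abmd)))
      bundle$binding_abmd <- binding_result(wt$dg_abmd, mu$dg_abmd,
                                            plan$temperature, "ABMD")
    bundle$diff_map_free <- mean_map("MUT_free") - mean_map("WT_free")
    bundle$hb_significance <- tryCatch(
      hbond_count_significance(unlist(wt$hb_frame_totals),
                               unlist(mu$hb_frame_totals)),
      error = function(e) NA_real_)
  }
  if (have("WT_clamped") && have("MUT_clamped")) {
    bundle$diff_map_clamped <- mean_map("MUT_clamped") - mean_map("WT_clamped")
  }
  if (!is.null(bundle$diff_map_free) && !is.null(bundle$diff_map_clamped)) {
    bundle$attenuation <- list(
      norm_free = sum(abs(bundle$diff_map_free)),
      norm_clamped = sum(abs(bundle$diff_map_clamped)))
    bundle$attenuation$attenuated <-
      bundle$attenuation$norm_clamped < bundle$attenuation$norm_free
  }
  if (all(vapply(c("WT_clamped", "MUT_clamped", "WT_free", "MUT_free"),
                 have, logical(1)))) {
    cts <- lapply(c("WT_clamped", "MUT_clamped", "WT_free", "MUT_free"),
                  sum_counts)
    pairs <- sort(unique(unlist(lapply(cts, names))))
    getc <- function(ct) ifelse(pairs %in% names(ct), ct[pairs], 0)
    bundle$hbr <- hbr_table(pairs, getc(cts[[1]]), getc(cts[[2]]),
                            getc(cts[[3]]), getc(cts[[4]]))
  }
  class(bundle) <- "report_bundle"
  if (!is.null(plan$output_dir)) write_bundle_tsv(bundle, plan$output_dir)
  bundle
}

write_bundle_tsv <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$hbr))
    utils::write.table(bundle$hbr, file.path(dir, "hbr_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("diff_map_free", "diff_map_clamped")) {
    if (!is.null(bundle[[nm]]))
      utils::write.table(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE)
  }
  writeLines(render_report(bundle), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a comparative report
#'
#' Deterministic markdown summary of a bundle: a binding-energy block (per
#' variant means with replicate spread, the mutant penalty and the implied
#' dissociation-constant fold change), a hydrogen-bond ratio block, and the
#' clamp-attenuation summary. Rendering twice yields identical bytes.
#'
#' @param bundle a `report_bundle` from [run_experiment()]
#' @return character vector of markdown lines
#' @export
render_report <- function(bundle) {
  ln <- c("# Toy-dimer comparative binding report", "")
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  for (br_name in c("binding_abmd", "binding_endstate")) {
    br <- bundle[[br_name]]
    if (is.null(br)) next
    ln <- c(ln, sprintf("## Binding free energy (%s)", br$method), "",
            "| quantity | value (kcal/mol) |", "|---|---|",
            sprintf("| dG_WT | %s +/- %s |", fmt(br$dG_WT), fmt(br$dG_WT_se)),
            sprintf("| dG_MUT | %s +/- %s |", fmt(br$dG_MUT), fmt(br$dG_MUT_se)),
            sprintf("| ddG (MUT - WT) | %s +/- %s |", fmt(br$ddG), fmt(br$ddG_se)),
            sprintf("| Kd_MUT / Kd_WT | %s |", fmt(br$kd_ratio)), "")
  }
  if (!is.null(bundle$hbr)) {
    h <- bundle$hbr
    ln <- c(ln, "## Hydrogen-bond ratio table", "",
            "| pair | WT_clamped | MUT_clamped | HbR1 | WT_free | MUT_free | HbR2 | HbR1>HbR2 |",
            "|---|---|---|---|---|---|---|---|",
            sprintf("| %s | %g | %g | %s | %g | %g | %s | %s |",
                    h$pair, h$wt_clamped, h$mut_clamped,
                    fmt(round_half_down(h$hbr1, 2)),
                    h$wt_free, h$mut_free,
                    fmt(round_half_down(h$hbr2, 2)), h$flag), "")
  }
  if (!is.null(bundle$attenuation)) {
    at <- bundle$attenuation
    ln <- c(ln, "## Clamp attenuation", "",
            sprintf("- |MUT - WT| contact-difference norm, free: %s", fmt(at$norm_free, 3)),
            sprintf("- |MUT - WT| contact-difference norm, clamped: %s", fmt(at$norm_clamped, 3)),
            sprintf("- clamping attenuates the difference: %s", at$attenuated), "")
  }
  if (length(bundle$failures)) {
    ln <- c(ln, "## Failure manifest", "",
            sprintf("- %s: %s", names(bundle$failures),
                    unlist(bundle$failures)), "")
  }
  ln
}
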