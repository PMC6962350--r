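# End-to-end orchestration: mine/choose gates -> scan a target -> merge
# regions -> plan mutations -> place a heme -> clash screen -> report.

config_checksum <- function(lines) {
  # small deterministic checksum of the resolved configuration text
  bytes <- as.integer(charToRaw(paste(lines, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

#' Run the heme-site design pipeline
#'
#' Reads a target structure, computes backbone dihedrals, scans them
#' against a gate set, merges passing windows into candidate regions, plans
#' the CxxCH-creating mutations for each region, optionally places the
#' idealized heme on the best site and screens it for clashes, and writes
#' per-stage outputs plus a human-readable report and a machine-readable
#' run manifest.  Reruns with an identical configuration produce an
#' identical manifest checksum.
#'
#' @param target path to the target structure (PDB or mmCIF).
#' @param gates `"published"` or the path of a gates file
#'   ([write_gates()] format).
#' @param merge_mode `"window-starts"`, `"covered-residues"` or `"both"`.
#' @param clash_tolerance Angstrom margin below the vdW sum (see
#'   [clash_check()]).
#' @param place one of `"auto"` (first passing window, if any), `"none"`,
#'   or a `"CHAIN:START"` string.
#' @param out_dir output directory (created if needed).
#' @param seed integer recorded in the manifest (the design stages are
#'   deterministic; the seed is threaded through for provenance).
#' @param verbose log stage progress to stderr.
#' @return invisible list with `dihedrals`, `sites`, `regions`, `plans`,
#'   `placement`, `clashes`, `manifest`.
#' @export
run_pipeline <- function(target, gates = "published", merge_mode = "both",
                         clash_tolerance = 0.4, place = "auto",
                         out_dir = tempfile("hemesite_run_"), seed = 1L,
                         verbose = FALSE) {
  # validate before any computation
  if (!file.exists(target)) stop("startup error: target not found: ", target)
  if (!identical(gates, "published") && !file.exists(gates))
    stop("startup error: gates file not found: ", gates)
  if (!merge_mode %in% c("window-starts", "covered-residues", "both"))
    stop("startup error: invalid merge_mode '", merge_mode, "'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[hemesite] ", ...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  gate_set <- stage("gates", {
    if (identical(gates, "published")) published_gates() else read_gates(gates)
  })
  log_msg("gates: ", if (identical(gates, "published")) "published" else gates)

  st <- stage("read", read_structure(target))
  dih <- stage("dihedrals", compute_backbone_dihedrals(st))
  write_dihedral_csv(dih, file.path(out_dir, "dihedrals.csv"))

  sites <- stage("scan", gate_scan(dih, gate_set))
  utils::write.table(as.data.frame(sites), file.path(out_dir, "sites.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_msg("scan: ", sum(sites$pass), "/", nrow(sites), " windows pass")

  modes <- if (merge_mode == "both") c("window-starts", "covered-residues")
           else merge_mode
  regions <- stage("merge", do.call(rbind, lapply(modes, function(m)
    merge_regions(sites, mode = m, index_map = dih))))
  utils::write.table(as.data.frame(regions), file.path(out_dir, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  plans <- stage("plan", {
    first_mode_regions <- regions[regions$mode == modes[1L], , drop = FALSE]
    lapply(seq_len(nrow(first_mode_regions)), function(i) {
      r <- first_mode_regions[i, ]
      plan_mutations(chain_sequence(st, r$chain), r$start_index)
    })
  })
  if (length(plans)) {
    ptab <- do.call(rbind, lapply(plans, function(p)
      data.frame(start = p$start, window_before = p$window_before,
                 window_after = p$window_after,
                 n_substitutions = p$n_substitutions,
                 substitutions = paste(sprintf("%s%s%d%s",
                   p$substitutions$from, p$substitutions$position,
                   p$start + p$substitutions$offset - 1L,
                   p$substitutions$to), collapse = ","),
                 stringsAsFactors = FALSE)))
    utils::write.table(ptab, file.path(out_dir, "mutation_plans.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fasta <- unlist(lapply(seq_along(plans), function(i)
      c(sprintf(">design_site_%d window %d %s->%s", i, plans[[i]]$start,
                plans[[i]]$window_before, plans[[i]]$window_after),
        plans[[i]]$mutated_sequence)))
    writeLines(fasta, file.path(out_dir, "designs.fasta"))
  }

  placement <- NULL
  clashes <- NULL
  if (!identical(place, "none")) {
    site <- if (identical(place, "auto")) {
      p <- sites[sites$pass, , drop = FALSE]
      if (nrow(p)) list(chain = p$chain[1L], start_index = p$start_index[1L])
      else NULL
    } else {
      parts <- strsplit(place, ":", fixed = TRUE)[[1L]]
      list(chain = parts[1L], start_index = as.integer(parts[2L]))
    }
    if (!is.null(site)) {
      placement <- stage("place", place_heme(st, site))
      clashes <- stage("clash",
                       clash_check(st, placement, tolerance = clash_tolerance))
      utils::write.table(clashes$pairs, file.path(out_dir, "clashes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_pdb(st, file.path(out_dir, "complex.pdb"), heme = placement$atoms)
      log_msg("placed heme at ", site$chain, ":", site$start_index,
              " (", clashes$n_clashes, " clashes)")
    }
  }

  cfg <- c(paste0("target=", normalizePath(target)),
           paste0("gates=", if (identical(gates, "published")) "published"
                  else normalizePath(gates)),
           paste0("merge_mode=", merge_mode),
           paste0("clash_tolerance=", clash_tolerance),
           paste0("place=", place),
           paste0("seed=", seed),
           paste0("package_version=",
                  as.character(utils::packageVersion("hemesite"))))
  manifest <- c(cfg, paste0("config_checksum=", config_checksum(cfg)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  report <- c(
    "hemesite design report",
    "======================",
    sprintf("target: %s", target),
    sprintf("windows scanned: %d, passing: %d", nrow(sites), sum(sites$pass)),
    "",
    "candidate regions:",
    if (nrow(regions)) sprintf("  %s [%s] residues %d-%d (auth %s-%s, %d windows)",
        regions$chain, regions$mode, regions$start_index, regions$end_index,
        regions$start_auth, regions$end_auth, regions$n_windows)
    else "  (none)",
    "",
    "mutation plans:",
    if (length(plans)) vapply(plans, function(p)
      sprintf("  window %d: %s -> %s (%d substitutions)", p$start,
              p$window_before, p$window_after, p$n_substitutions),
      character(1L))
    else "  (none)",
    "",
    if (!is.null(clashes))
      sprintf("heme placement: anchor rmsd %.3f A, %d clash(es) -> %s",
              placement$anchor_rmsd, clashes$n_clashes,
              if (clashes$pass) "PASS" else "FAIL")
    else "heme placement: (skipped)"
  )
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(dihedrals = dih, sites = sites, regions = regions,
                 plans = plans, placement = placement, clashes = clashes,
                 manifest = manifest, out_dir = out_dir))
}

#' Command-line entry point
#'
#' In-process dispatcher behind the `hemesite` Rscript executable
#' (`inst/exec/hemesite`).  Subcommands: `scan`, `run`, `fit-nernst`,
#' `quantify-heme`, `speciate`, `charge`, `dls-average`, `simulate`.
#' Writes results to stdout or `--out`; returns the exit status invisibly.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: hemesite <scan|run|fit-nernst|quantify-heme|speciate|charge|dls-average|simulate> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i[1L] < length(rest)) rest[i[1L] + 1L] else default
  }
  status <- 0L
  switch(cmd,
    "scan" = ,
    "run" = {
      res <- run_pipeline(
        target = opt("--target"),
        gates = opt("--gates", "published"),
        merge_mode = opt("--merge-mode", "both"),
        clash_tolerance = as.numeric(opt("--tolerance", "0.4")),
        place = if (cmd == "scan") "none" else opt("--site", "auto"),
        out_dir = opt("--out", "hemesite_out"),
        seed = as.integer(opt("--seed", "1")),
        verbose = "--verbose" %in% rest)
      cat(readLines(file.path(res$out_dir, "report.txt")), sep = "\n")
    },
    "fit-nernst" = {
      tab <- utils::read.table(opt("--in"), header = FALSE,
                               col.names = c("E", "A"))
      fit <- fit_nernst(tab, n = {
        nv <- opt("--n", "1"); if (nv == "free") "free" else as.numeric(nv)
      }, temperature = as.numeric(opt("--temperature", "298.15")))
      print(fit)
    },
    "quantify-heme" = {
      cat(sprintf("%.4f uM\n", beer_lambert_concentration(
        as.numeric(opt("--absorbance")),
        as.numeric(opt("--epsilon", "1e5")),
        as.numeric(opt("--path", "1")))))
    },
    "speciate" = {
      cat(sprintf("%.4f\n", hh_ionized(as.numeric(opt("--total")),
                                       as.numeric(opt("--ph")),
                                       as.numeric(opt("--pka", "9.21")))))
    },
    "charge" = {
      seqs <- opt("--sequence")
      ph <- as.numeric(opt("--ph", "8.8"))
      cat(sprintf("net charge at pH %.2f: %+.3f (pI %.2f)\n", ph,
                  net_charge(seqs, ph), isoelectric_point(seqs)))
    },
    "dls-average" = {
      tab <- utils::read.table(opt("--in"), header = FALSE,
                               col.names = c("radius", "weight"))
      cat(sprintf("%.4f nm\n", mass_weighted_radius(tab)))
    },
    "simulate" = {
      what <- opt("--what", "titration")
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out", paste0("hemesite_", what, ".txt"))
      if (what == "titration") {
        curve <- make_titration(sigma = as.numeric(opt("--sigma", "0.02")),
                                seed = seed)
        utils::write.table(curve, out, row.names = FALSE, col.names = FALSE)
      } else if (what == "backbone") {
        n <- as.integer(opt("--length", "30"))
        write_pdb(make_backbone(rep(-57, n), rep(-47, n)), out)
      } else if (what == "motifs") {
        mc <- make_motif_chain(seed = seed)
        write_pdb(mc$structure, out)
      } else stop("unknown simulate target: ", what)
      cat("wrote ", out, "\n", sep = "")
    },
    {
      cat("unknown subcommand: ", cmd, "\n", sep = "")
      status <- 1L
    })
  invisible(status)
}
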