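#' Build a pipeline configuration
#'
#' Collects every tunable of the design pipeline with its default. All
#' defaults are config-exposed; [run_pipeline()] echoes the effective values
#' in its run record.
#'
#' @param structure Optional template atom tibble; `NULL` generates the
#'   default synthetic bundle.
#' @param chain Cytokine chain id.
#' @param ranges Helix ranges (list of `c(start, end)`), or `NULL` for the
#'   bundle's declared ranges (auto-assignment when a user structure comes
#'   without ranges).
#' @param receptor_chains Receptor chain ids present in `structure`.
#' @param receptor_targets For the synthetic bundle: helix ids to receive a
#'   receptor probe.
#' @param contact_cutoff,min_contacts Interface-contact parameters (Angstrom,
#'   count).
#' @param fix_first Helix pinned to the design N-terminus.
#' @param span_per_residue,slack_residues Connector sizing parameters.
#' @param closure_tolerance,max_iter,n_trajectories CCD parameters.
#' @param clash_threshold,min_sequence_separation Clash detection parameters.
#' @param staple Scan for and apply a disulfide staple.
#' @param staple_regions Optional list of two design-position ranges; default
#'   is the first and last template helices.
#' @param cb_window Cbeta-Cbeta window for staple scanning (Angstrom).
#' @param mutations Optional compact mutation string (e.g. `"Q6P,T45I"`)
#'   applied after stapling.
#' @param rmsd_threshold Acceptance RMSD (strict `<`, Angstrom).
#' @param perturb_sd Gaussian coordinate noise injected before validation
#'   (Angstrom); exercises the rejection/retry branch.
#' @param retry_cap Rebuild attempts after a rejected validation.
#' @param seed Master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(structure = NULL, chain = "A", ranges = NULL,
                            receptor_chains = character(),
                            receptor_targets = c("H1", "H3"),
                            contact_cutoff = 4.5, min_contacts = 5L,
                            fix_first = "H1",
                            span_per_residue = 3.8, slack_residues = 1L,
                            closure_tolerance = 0.5, max_iter = 500L,
                            n_trajectories = 10L,
                            clash_threshold = 2.6, min_sequence_separation = 3L,
                            staple = TRUE, staple_regions = NULL,
                            cb_window = c(3.0, 5.0),
                            mutations = NULL,
                            rmsd_threshold = 1.0,
                            perturb_sd = 0,
                            retry_cap = 10L,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full design pipeline
#'
#' Executes annotate -> blueprint -> build -> stabilize -> validate. On a
#' rejected validation the assembly is retried with the next connector seed,
#' up to `retry_cap` attempts. Deterministic given the config and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_record`: per-stage log, blueprint, roles, clash report,
#'   staples applied, final model, validation result, and the full config
#'   echo.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- tibble::tibble(stage = stage, detail = detail)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- annotate ---------------------------------------------------------------
  ann <- run_stage("annotate", {
    if (is.null(cfg$structure)) {
      bundle <- make_ideal_bundle(seed = cfg$seed)
      if (length(cfg$receptor_targets)) {
        bundle <- make_receptor_probe(bundle, cfg$receptor_targets)
        cfg$receptor_chains <- "R"
      }
      s <- bundle$structure
      ranges <- bundle$ranges
    } else {
      s <- cfg$structure
      ranges <- cfg$ranges %||% assign_helices_auto(s, cfg$chain)
      if (length(ranges) < 2L) stop("fewer than 2 helices found")
    }
    helices <- extract_helices(s, cfg$chain, ranges)
    roles <- assign_roles(s, helices, cfg$chain, cfg$receptor_chains,
                          cfg$contact_cutoff, cfg$min_contacts)
    list(s = s, helices = helices, roles = roles)
  })
  note("annotate", sprintf("%d helices; roles: %s", nrow(ann$helices),
                           paste(ann$roles$role, collapse = ",")))

  # -- blueprint --------------------------------------------------------------
  bp <- run_stage("blueprint", design_blueprint(
    ann$helices, ann$roles, fix_first = cfg$fix_first,
    span_per_residue = cfg$span_per_residue, slack_residues = cfg$slack_residues))
  note("blueprint", sprintf("order %s; economy %d",
                            paste(bp$order, collapse = ">"), bp$economy))

  # -- build / stabilize / validate with retry --------------------------------
  attempt <- 0L
  result <- NULL
  repeat {
    model <- run_stage("build", assemble_model(
      ann$s, ann$helices, bp, seed = cfg$seed + attempt * 100L,
      tolerance = cfg$closure_tolerance, max_iter = cfg$max_iter,
      n_trajectories = cfg$n_trajectories))
    if (cfg$perturb_sd > 0) {
      model <- perturb_coordinates(model, cfg$perturb_sd, cfg$seed + attempt)
    }
    clashes <- run_stage("build", detect_clashes(model, cfg$clash_threshold,
                                                 cfg$min_sequence_separation))

    staples_applied <- tibble::tibble(pos_i = integer(), pos_j = integer(),
                                      cb_distance = numeric(), geometry_score = numeric())
    model <- run_stage("stabilize", {
      if (isTRUE(cfg$staple)) {
        regions <- cfg$staple_regions %||% {
          prov <- model$provenance
          span_of <- function(id) range(prov$design_pos[!is.na(prov$helix_id) & prov$helix_id == id])
          list(span_of(ann$helices$helix_id[1]),
               span_of(ann$helices$helix_id[nrow(ann$helices)]))
        }
        staples <- scan_disulfide_sites(model, regions[[1]], regions[[2]], cfg$cb_window)
        if (nrow(staples) > 0L) {
          best <- staples[1, ]
          seqc <- strsplit(model$sequence, "")[[1]]
          staple_muts <- tibble::tibble(
            position = c(best$pos_i, best$pos_j),
            wt_aa = seqc[c(best$pos_i, best$pos_j)],
            mut_aa = "C")
          model <- apply_mutations(model, staple_muts)
          staples_applied <- best
        }
      }
      if (!is.null(cfg$mutations)) model <- apply_mutations(model, cfg$mutations)
      model
    })
    note("stabilize", sprintf("attempt %d: %d clash pair(s); %d staple(s) applied",
                              attempt, nrow(clashes$pairs), nrow(staples_applied)))

    val <- run_stage("validate", accept_design(model, ann$s, cfg$rmsd_threshold))
    note("validate", sprintf("attempt %d: rmsd %.3f A -> %s", attempt, val$rmsd,
                             if (val$accepted) "accepted" else "rejected"))
    if (val$accepted || attempt >= cfg$retry_cap) {
      result <- list(model = model, clashes = clashes,
                     staples = staples_applied, validation = val)
      break
    }
    attempt <- attempt + 1L
  }

  structure(list(
    stages = dplyr::bind_rows(log),
    helices = ann$helices,
    roles = ann$roles,
    blueprint = bp,
    clashes = result$clashes,
    staples = result$staples,
    model = result$model,
    validation = result$validation,
    accepted = result$validation$accepted,
    rejection_cause = if (result$validation$accepted) NA_character_ else
      sprintf("rmsd %.3f A >= threshold %.2f A after %d attempt(s)",
              result$validation$rmsd, cfg$rmsd_threshold, attempt + 1L),
    attempts = attempt + 1L,
    config = cfg
  ), class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record> ", if (x$accepted) "ACCEPTED" else "REJECTED",
      " after ", x$attempts, " attempt(s); order ",
      paste(x$blueprint$order, collapse = ">"),
      "; final rmsd ", format(round(x$validation$rmsd, 4), nsmall = 4), " A\n", sep = "")
  print(x$stages, n = Inf)
  invisible(x)
}

#' @method tidy run_record
#' @export
tidy.run_record <- function(x, ...) x$stages

#' @method glance run_record
#' @export
glance.run_record <- function(x, ...) {
  tibble::tibble(
    accepted = x$accepted,
    attempts = x$attempts,
    order = paste(x$blueprint$order, collapse = ">"),
    economy = x$blueprint$economy,
    n_clashes = nrow(x$clashes$pairs),
    n_staples = nrow(x$staples),
    rmsd = x$validation$rmsd,
    max_closure_error = max(c(0, x$model$closure_errors))
  )
}
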