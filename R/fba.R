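# Stoichiometric models, LP-based growth maximization, and the
# metabolite-producibility screen.

#' Construct a stoichiometric metabolic model
#'
#' @param id model name.
#' @param reactions list of reactions, each a list with `id`, `stoich`
#'   (named numeric, negative = consumed), `lb`, `ub` (flux bounds in
#'   mmol h^-1 gDW^-1).
#' @param biomass id of the biomass (growth) reaction.
#' @param exchanges named character vector metabolite -> exchange reaction
#'   id; when omitted, single-metabolite boundary reactions are
#'   auto-detected as exchanges.
#' @param metabolites optional metabolite universe (defaults to all
#'   metabolites referenced by reactions; extra declared metabolites that
#'   no reaction touches are rejected as dangling).
#' @return A validated `metabolic_model`.
#' @export
metabolic_model <- function(id, reactions, biomass, exchanges = NULL,
                            metabolites = NULL) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  if (is.null(metabolites)) metabolites <- used
  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions, biomass = biomass,
                          exchanges = exchanges),
                     class = "metabolic_model")
  validate_model(model)
}

#' Validate a metabolic model
#'
#' Checks: biomass reaction present; lower <= upper bound on every
#' reaction; no zero stoichiometric coefficients; no dangling metabolites
#' (declared but used by no reaction). Exchanges are auto-detected as
#' single-metabolite boundary reactions when not annotated.
#'
#' @param model a `metabolic_model`.
#' @return The model, with `exchanges` filled in.
#' @export
validate_model <- function(model) {
  rx <- model$reactions
  if (is.null(model$biomass) || !model$biomass %in% names(rx))
    stop("missing biomass reaction", if (!is.null(model$biomass))
      paste0(": ", model$biomass))
  for (r in rx) {
    if (r$lb > r$ub)
      stop("reaction ", r$id, ": lower bound exceeds upper bound")
    if (any(r$stoich == 0))
      stop("reaction ", r$id, ": zero stoichiometric coefficient")
  }
  used <- unique(unlist(lapply(rx, function(r) names(r$stoich))))
  dangling <- setdiff(model$metabolites, used)
  if (length(dangling))
    stop("dangling metabolite(s): ", paste(dangling, collapse = ", "))
  if (is.null(model$exchanges)) {
    ex <- Filter(function(r) length(r$stoich) == 1 && r$id != model$biomass, rx)
    model$exchanges <- stats::setNames(vapply(ex, `[[`, "", "id"),
                                       vapply(ex, function(r) names(r$stoich), ""))
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions (%d exchanges), biomass = %s\n",
              x$id, length(x$metabolites), length(x$reactions),
              length(x$exchanges), x$biomass))
  invisible(x)
}

#' Load a metabolic model from JSON or an SBML subset
#'
#' JSON dialect: `{metabolites: [...], reactions: [{id, stoich: {met: coef},
#' lb, ub}], biomass, exchanges: {met: rxn}}`. The SBML subset reads
#' species, reactions, stoichiometries and the `reversible` flag (bounds
#' -1000..1000 for reversible, 0..1000 otherwise); the biomass reaction is
#' recognized by id (case-insensitive match on "biomass") unless given.
#'
#' @param path file to read.
#' @param dialect `"json"` or `"sbml-subset"`.
#' @param biomass biomass reaction id (SBML only; default autodetected).
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, dialect = c("json", "sbml-subset"),
                       biomass = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    rxns <- lapply(j$reactions, function(r)
      list(id = r$id, stoich = unlist(r$stoich), lb = r$lb, ub = r$ub))
    ex <- if (!is.null(j$exchanges)) unlist(j$exchanges) else NULL
    return(metabolic_model(id = if (is.null(j$id)) basename(path) else j$id,
                           reactions = rxns, biomass = j$biomass,
                           exchanges = ex,
                           metabolites = unlist(j$metabolites)))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"),
                            "id")
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    sto <- function(xp, sign) {
      refs <- xml2::xml_find_all(rn, xp)
      stats::setNames(
        sign * as.numeric(ifelse(is.na(xml2::xml_attr(refs, "stoichiometry")),
                                 1, xml2::xml_attr(refs, "stoichiometry"))),
        xml2::xml_attr(refs, "species"))
    }
    s <- c(sto(".//listOfReactants/speciesReference", -1),
           sto(".//listOfProducts/speciesReference", 1))
    list(id = rid, stoich = s, lb = if (rev) -1000 else 0, ub = 1000)
  })
  if (is.null(biomass)) {
    ids <- vapply(rxns, `[[`, "", "id")
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit) != 1) stop("missing biomass reaction: cannot autodetect")
    biomass <- hit
  }
  metabolic_model(id = basename(path), reactions = rxns, biomass = biomass,
                  metabolites = species)
}

#' Write a model to the JSON dialect
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(id = model$id, metabolites = as.list(model$metabolites),
              reactions = lapply(unname(model$reactions), function(r)
                list(id = r$id, stoich = as.list(r$stoich),
                     lb = r$lb, ub = r$ub)),
              biomass = model$biomass,
              exchanges = as.list(model$exchanges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a model as an SBML subset
#' @inheritParams write_model_json
#' @export
write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  sp <- paste(sprintf('      <species id="%s"/>', esc(model$metabolites)),
              collapse = "\n")
  rx <- vapply(model$reactions, function(r) {
    refs <- function(mets, coefs) paste(
      sprintf('          <speciesReference species="%s" stoichiometry="%s"/>',
              esc(mets), format(coefs, digits = 15)), collapse = "\n")
    st <- r$stoich
    sub <- names(st)[st < 0]; prod <- names(st)[st > 0]
    paste0(sprintf('      <reaction id="%s" reversible="%s">\n', esc(r$id),
                   tolower(r$lb < 0)),
           if (length(sub)) paste0("        <listOfReactants>\n",
                                   refs(sub, -st[sub]),
                                   "\n        </listOfReactants>\n") else "",
           if (length(prod)) paste0("        <listOfProducts>\n",
                                    refs(prod, st[prod]),
                                    "\n        </listOfProducts>\n") else "",
           "      </reaction>")
  }, "")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
                '  <model id="', esc(model$id), '">\n',
                "    <listOfSpecies>\n", sp, "\n    </listOfSpecies>\n",
                "    <listOfReactions>\n", paste(rx, collapse = "\n"),
                "\n    </listOfReactions>\n  </model>\n</sbml>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Configuration of the producibility screen
#'
#' Mirrors the simulation background of the screen: a minimal medium with
#' D-glucose removed, oxygen uptake set per scenario (anoxic 0,
#' microaerobic 1, aerobic 10 mmol h^-1 gDW^-1), each source metabolite
#' supplied individually at 100 mmol h^-1 gDW^-1, a requirement that at
#' least 50% of the maximal growth rate is maintained, and a producibility
#' call at maximum target flux > 1e-6.
#'
#' @param medium named numeric: metabolite -> maximal uptake rate. The
#'   shipped default is an empty placeholder; supply the model's minimal
#'   medium composition explicitly.
#' @param remove_glucose drop `glucose_id` from the medium (default TRUE).
#' @param glucose_id metabolite id of D-glucose in the model namespace.
#' @param oxygen_levels named uptake rates per scenario.
#' @param oxygen_id metabolite id of oxygen.
#' @param source_uptake uptake rate granted to the source metabolite.
#' @param growth_fraction fraction of maximal growth that must be kept.
#' @param producibility_epsilon strict threshold for the producibility call.
#' @param solver_tolerance negative fluxes above `-solver_tolerance` are
#'   clamped to zero before the epsilon call.
#' @export
fva_config <- function(medium = numeric(0), remove_glucose = TRUE,
                       glucose_id = "glc__D", oxygen_id = "o2",
                       oxygen_levels = c(anoxic = 0, microaerobic = 1,
                                         aerobic = 10),
                       source_uptake = 100, growth_fraction = 0.5,
                       producibility_epsilon = 1e-6,
                       solver_tolerance = 1e-9) {
  if (any(c(medium, oxygen_levels, source_uptake) < 0))
    stop_invalid("uptake rates must be nonnegative")
  if (growth_fraction <= 0 || growth_fraction > 1)
    stop_invalid("growth_fraction must lie in (0, 1]")
  structure(list(medium = medium, remove_glucose = remove_glucose,
                 glucose_id = glucose_id, oxygen_id = oxygen_id,
                 oxygen_levels = oxygen_levels, source_uptake = source_uptake,
                 growth_fraction = growth_fraction,
                 producibility_epsilon = producibility_epsilon,
                 solver_tolerance = solver_tolerance),
            class = "fva_config")
}

ensure_exchange <- function(model, met, prefix = "EX_") {
  if (met %in% names(model$exchanges)) return(model)
  rid <- paste0(prefix, met)
  model$reactions[[rid]] <- list(id = rid,
                                 stoich = stats::setNames(-1, met),
                                 lb = 0, ub = 1000)
  model$exchanges <- c(model$exchanges, stats::setNames(rid, met))
  model
}

#' Constrain a model to a medium, oxygen scenario and source metabolite
#'
#' Closes uptake through every exchange, reopens the medium components at
#' their configured rates (minus D-glucose when `remove_glucose`), sets the
#' oxygen uptake bound to the scenario value, and grants the source
#' metabolite `source_uptake` (adding an exchange reaction for it if the
#' model has none). Exchange flux convention: negative = uptake, positive =
#' secretion; secretion stays open.
#'
#' @param model a [metabolic_model()].
#' @param cfg an [fva_config()].
#' @param oxygen_scenario name in `cfg$oxygen_levels`.
#' @param source source metabolite id, or `NULL` for the medium-only
#'   control condition.
#' @return The constrained model.
#' @export
apply_medium <- function(model, cfg, oxygen_scenario = "anoxic",
                         source = NULL) {
  stopifnot(inherits(cfg, "fva_config"))
  if (!oxygen_scenario %in% names(cfg$oxygen_levels))
    stop("unknown oxygen scenario: ", oxygen_scenario)
  if (!is.null(source) && !source %in% model$metabolites)
    stop("source metabolite not in model: ", source)
  medium <- cfg$medium
  if (cfg$remove_glucose) medium <- medium[setdiff(names(medium), cfg$glucose_id)]
  for (met in names(model$exchanges))
    model$reactions[[model$exchanges[[met]]]]$lb <- 0
  for (met in names(medium)) {
    model <- ensure_exchange(model, met)
    model$reactions[[model$exchanges[[met]]]]$lb <- -medium[[met]]
  }
  model <- ensure_exchange(model, cfg$oxygen_id)
  model$reactions[[model$exchanges[[cfg$oxygen_id]]]]$lb <-
    -cfg$oxygen_levels[[oxygen_scenario]]
  if (!is.null(source)) {
    model <- ensure_exchange(model, source)
    model$reactions[[model$exchanges[[source]]]]$lb <- -cfg$source_uptake
  }
  model
}

# --- LP layer -------------------------------------------------------------

#' Solve a bounded steady-state LP over a model
#'
#' Maximizes (or minimizes) a linear flux objective subject to the
#' steady-state constraint S v = 0 and the reaction bounds, plus optional
#' extra linear constraints. Solved by the package's dense two-phase
#' primal simplex (Bland's rule) after shifting fluxes to the nonnegative
#' orthant.
#'
#' @param model a [metabolic_model()].
#' @param objective named coefficients over reaction ids.
#' @param extra list of constraints, each `list(coef = <named>, dir =
#'   ">="|"<=", rhs = <num>)`.
#' @param maximize direction.
#' @return list: `status` (`"optimal"`, `"infeasible"`, `"unsolved"`),
#'   `objective` value, `fluxes` (named, only when optimal).
#' @keywords internal
#' @export
fba_solve <- function(model, objective, extra = list(), maximize = TRUE) {
  rids <- names(model$reactions)
  mets <- sort(unique(unlist(lapply(model$reactions, function(r) names(r$stoich)))))
  nv <- length(rids)
  S <- matrix(0, length(mets), nv, dimnames = list(mets, rids))
  for (r in model$reactions) S[names(r$stoich), r$id] <- r$stoich
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- stats::setNames(numeric(nv), rids)
  obj[names(objective)] <- objective
  Age <- NULL; bge <- NULL
  for (cn in extra) {
    a <- stats::setNames(numeric(nv), rids)
    a[names(cn$coef)] <- cn$coef
    rhs <- cn$rhs
    if (cn$dir == "<=") { a <- -a; rhs <- -rhs }
    Age <- rbind(Age, a); bge <- c(bge, rhs)
  }
  sol <- solve_lp_bounded(obj, S, numeric(nrow(S)), lb, ub,
                          Age = Age, bge = bge, maximize = maximize)
  if (sol$status != "optimal")
    return(list(status = sol$status, objective = NA_real_))
  list(status = "optimal", objective = sol$objective,
       fluxes = stats::setNames(sol$v, rids))
}

#' Maximal growth rate
#'
#' Maximizes flux through the biomass reaction subject to steady state and
#' the current bounds. Infeasibility is reported as a status, not an error.
#'
#' @param model a constrained [metabolic_model()].
#' @return list: `mu` (optimal biomass flux, `NA` when not optimal),
#'   `status`.
#' @export
max_growth <- function(model) {
  sol <- fba_solve(model, stats::setNames(1, model$biomass))
  list(mu = sol$objective, status = sol$status)
}

#' Producibility call from a maximal flux
#'
#' Clamps solver noise in `(-solver_tolerance, 0)` to zero, then applies
#' the strict rule `flux > producibility_epsilon`.
#'
#' @param flux maximal production flux.
#' @param cfg an [fva_config()].
#' @return logical.
#' @export
flux_epsilon_call <- function(flux, cfg = fva_config()) {
  if (flux < -cfg$solver_tolerance)
    stop("production flux substantially negative: ", flux)
  flux <- max(flux, 0)
  flux > cfg$producibility_epsilon
}

#' Source-to-target producibility screen
#'
#' For every source metabolite and oxygen scenario: constrain the model
#' with [apply_medium()], maximize growth, fix biomass to at least
#' `growth_fraction` of that maximum, then maximize the flux of each
#' target's exchange reaction (adding a demand reaction when the target has
#' no exchange). A target is called producible when its maximal flux
#' exceeds `producibility_epsilon`. When no growth is possible the growth
#' constraint is vacuous (biomass >= 0) and rows are flagged
#' `zero_growth`; an infeasible scenario reports all targets
#' non-producible with status `infeasible`. All oxygen scenarios are always
#' reported.
#'
#' @param model a [metabolic_model()].
#' @param cfg an [fva_config()].
#' @param sources,targets metabolite ids (model namespace).
#' @return data.frame: `source`, `target`, `oxygen`, `mu_max`, `max_flux`,
#'   `producible`, `status`.
#' @export
production_screen <- function(model, cfg, sources, targets) {
  out <- list()
  for (src in sources) {
    for (ox in names(cfg$oxygen_levels)) {
      m <- apply_medium(model, cfg, oxygen_scenario = ox, source = src)
      g <- max_growth(m)
      if (g$status != "optimal") {
        out[[length(out) + 1L]] <- data.frame(
          source = src, target = targets, oxygen = ox, mu_max = NA_real_,
          max_flux = 0, producible = FALSE, status = g$status,
          stringsAsFactors = FALSE)
        next
      }
      mu <- g$mu
      status <- if (mu > cfg$solver_tolerance) "ok" else "zero_growth"
      extra <- if (mu > cfg$solver_tolerance)
        list(list(coef = stats::setNames(1, m$biomass), dir = ">=",
                  rhs = cfg$growth_fraction * mu))
      else list()
      for (tg in targets) {
        m2 <- ensure_exchange(m, tg, prefix = if (tg %in% names(m$exchanges))
          "EX_" else "DM_")
        sol <- fba_solve(m2, stats::setNames(1, m2$exchanges[[tg]]),
                         extra = extra)
        flux <- if (sol$status == "optimal") max(sol$objective, 0) else 0
        out[[length(out) + 1L]] <- data.frame(
          source = src, target = tg, oxygen = ox, mu_max = mu,
          max_flux = flux,
          producible = sol$status == "optimal" && flux_epsilon_call(flux, cfg),
          status = if (sol$status == "optimal") status else sol$status,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
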