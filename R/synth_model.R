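# Toy central-metabolism network: a compartmentalized (cytosol c, plastid p,
# mitochondrion m) sketch of sugar uptake, glycolysis, the oxidative pentose
# phosphate route, TCA-driven ATP formation, fatty-acid/TAG synthesis, starch
# synthesis and protein synthesis, joined by inter-compartment transporters
# and drained by a composition-parameterized biomass reaction. The topology
# ships as a versioned JSON fixture (inst/extdata/toy_model.json); generators
# re-parameterize the biomass but never regenerate the topology.

#' Build the toy central-metabolism model in code
#'
#' Constructs the same network as the shipped `toy_model.json` fixture, with
#' neutral biomass coefficients. Used to (re)generate the fixture; analysis
#' code should load the fixture via [toy_model()].
#'
#' @return a `stoich_model`.
#' @export
build_toy_model <- function() {
  comp <- c(Glc_c = "c", G6P_c = "c", PYR_c = "c", FA_c = "c", TAG_c = "c",
            AA_c = "c", Protein_c = "c", ATP_c = "c", CO2_c = "c",
            G6P_p = "p", PYR_p = "p", AcCoA_p = "p", FA_p = "p",
            ADPG_p = "p", Starch_p = "p",
            PYR_m = "m", CO2_m = "m", ATP_m = "m")
  mets <- data.frame(id = names(comp), name = names(comp),
                     compartment = unname(comp), stringsAsFactors = FALSE)
  rx <- function(id, st, pathway, compartment, lb = 0, ub = 1000,
                 genes = character(0), exchange = FALSE)
    list(id = id, name = id, stoichiometry = st, lower_bound = lb,
         upper_bound = ub, pathway = pathway, compartment = compartment,
         genes = genes, exchange = exchange)
  reactions <- list(
    rx("EX_glc", c(Glc_c = 1), "sugar_uptake", "c", ub = 10, exchange = TRUE),
    rx("HXK_c", c(Glc_c = -1, G6P_c = 1), "glycolysis", "c"),
    rx("GLYC_c", c(G6P_c = -1, PYR_c = 2), "glycolysis", "c"),
    rx("GPT_cp", c(G6P_c = -1, G6P_p = 1), "transport", "cp"),
    rx("GLYC_p", c(G6P_p = -1, PYR_p = 2), "glycolysis", "p"),
    rx("OPP_p", c(G6P_p = -1, PYR_p = 2), "pentose_phosphate", "p"),
    rx("PYR_cp", c(PYR_c = -1, PYR_p = 1), "transport", "cp"),
    rx("PYR_cm", c(PYR_c = -1, PYR_m = 1), "transport", "cm"),
    rx("PDH_p", c(PYR_p = -1, AcCoA_p = 1), "fatty_acid_synthesis", "p"),
    rx("FAS_p", c(AcCoA_p = -3, FA_p = 1), "fatty_acid_synthesis", "p"),
    rx("FAX_pc", c(FA_p = -1, FA_c = 1), "transport", "pc"),
    rx("TAGS_c", c(FA_c = -1, TAG_c = 1), "tag_synthesis", "c"),
    rx("AGP_p", c(G6P_p = -1, ADPG_p = 1), "starch_synthesis", "p"),
    rx("SS_p", c(ADPG_p = -1, Starch_p = 1), "starch_synthesis", "p"),
    rx("AAS_c", c(PYR_c = -1, AA_c = 1), "protein_synthesis", "c"),
    rx("PROT_c", c(AA_c = -2, Protein_c = 1), "protein_synthesis", "c"),
    rx("TCA_m", c(PYR_m = -1, CO2_m = 3, ATP_m = 5), "tca", "m"),
    rx("ATP_mc", c(ATP_m = -1, ATP_c = 1), "transport", "mc"),
    rx("CO2_mc", c(CO2_m = -1, CO2_c = 1), "transport", "mc"),
    rx("EX_co2", c(CO2_c = -1), "exchange", "c", exchange = TRUE),
    rx("BIOMASS", c(TAG_c = -1/3, Starch_p = -1/3, Protein_c = -1/3,
                    ATP_c = -1), "biomass", "c"))
  stoich_model(mets, reactions, "BIOMASS")
}

#' Load the shipped toy model fixture
#' @return a `stoich_model` read from `inst/extdata/toy_model.json`.
#' @export
toy_model <- function() {
  load_model(system.file("extdata", "toy_model.json", package = "fluxcord",
                         mustWork = TRUE))
}

# ATP demand per unit biomass: lipid synthesis is the costliest sink
.atp_coeff <- function(lipid, starch) {
  protein <- 1 - lipid - starch
  2 * lipid + 0.5 * starch + 1 * protein
}

#' Re-parameterize the toy model's biomass composition
#'
#' Sets the biomass reaction's TAG, starch and protein coefficients to the
#' given fractions (the remainder of lipid + starch is protein) and the ATP
#' maintenance coefficient to a composition-weighted demand (lipid synthesis
#' costliest).
#'
#' @param model a `stoich_model` with a `BIOMASS` reaction.
#' @param lipid_fraction,starch_fraction biomass fractions in \[0,1\],
#'   summing to at most 1.
#' @return the re-parameterized model.
#' @export
set_biomass_composition <- function(model, lipid_fraction, starch_fraction) {
  if (lipid_fraction < 0 || starch_fraction < 0 ||
      lipid_fraction + starch_fraction > 1)
    stop("compositions must lie in [0,1] with lipid + starch <= 1",
         call. = FALSE)
  protein <- 1 - lipid_fraction - starch_fraction
  i <- match("BIOMASS", reaction_ids(model))
  st <- c(TAG_c = -lipid_fraction, Starch_p = -starch_fraction,
          Protein_c = -protein,
          ATP_c = -.atp_coeff(lipid_fraction, starch_fraction))
  model$reactions[[i]]$stoichiometry <- st[st != 0]
  validate_model(model)
  model
}

#' Generate the two accession-specific model parameterizations
#'
#' Loads the toy network topology and produces two biomass variants: A
#' (high lipid) and B (high starch), per the configured compositions,
#' together with accession-specific flux-ratio constraints standing in for
#' the information a 13C-MFA would contribute (here: the split between the
#' plastidial glycolytic and oxidative pentose-phosphate routes). Both
#' variants are checked feasible with a positive biomass optimum.
#'
#' @param config a [scenario_config()].
#' @param base_model optional `stoich_model` to parameterize (defaults to the
#'   shipped fixture).
#' @return list with `model_a`, `model_b` (parameterized models),
#'   `ratio_constraints_a`, `ratio_constraints_b`, and `objective_a`,
#'   `objective_b` (the FBA optima).
#' @export
make_model_pair <- function(config, base_model = toy_model()) {
  stopifnot(inherits(config, "scenario_config"))
  model_a <- set_biomass_composition(base_model, config$lipid_fraction_a,
                                     config$starch_fraction_a)
  model_b <- set_biomass_composition(base_model, config$lipid_fraction_b,
                                     config$starch_fraction_b)
  # MFA-style flux-ratio constraints: OPP_p carries a fixed share of the
  # plastidial G6P-to-pyruvate conversion, differing between accessions
  ratios_a <- data.frame(numerator = "OPP_p", denominator = "GLYC_p",
                         ratio = 0.25, stringsAsFactors = FALSE)
  ratios_b <- data.frame(numerator = "OPP_p", denominator = "GLYC_p",
                         ratio = 1.0, stringsAsFactors = FALSE)
  opt <- lapply(list(a = list(model_a, ratios_a), b = list(model_b, ratios_b)),
                function(mv) {
    sol <- tryCatch(fba(mv[[1]], mv[[2]]), error = function(e)
      stop("infeasible parameterization: ", conditionMessage(e), call. = FALSE))
    sol$objective_value
  })
  if (opt$a <= .FEAS_TOL || opt$b <= .FEAS_TOL)
    stop("infeasible parameterization: biomass optimum is zero; the blocking ",
         "constraint is the substrate uptake bound on 'EX_glc' or a zero ",
         "biomass composition", call. = FALSE)
  list(model_a = model_a, model_b = model_b,
       ratio_constraints_a = ratios_a, ratio_constraints_b = ratios_b,
       objective_a = opt$a, objective_b = opt$b)
}

#' Generate synthetic per-accession FVA bound sets at scale
#'
#' Emulates the *output* of flux variability analysis for a configurable
#' number of reactions, so downstream stages can be exercised at the study's
#' reaction count without solving thousands of LPs: a quota of exactly
#' `floor(responsive_fraction * n_reactions)` reactions gets a planted flux
#' response (both bound magnitudes scaled up in one accession, direction
#' alternating T/S), the rest get identical bounds in both accessions.
#'
#' @param config a [scenario_config()]; uses `n_reactions`,
#'   `responsive_fraction` and `seed`.
#' @return list with `bounds_a`, `bounds_b` (`flux_bounds` data.frames) and
#'   `truth` (data.frame `reaction_id`, `direction` over `{T, S, N}`).
#' @export
simulate_flux_bounds <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 101L)
  n <- config$n_reactions
  rid <- sprintf("R%04d", seq_len(n))
  center <- stats::runif(n, 0.5, 5) * sample(c(-1, 1), n, replace = TRUE)
  half_width <- stats::runif(n, 0, 0.4)
  vmin_b <- center - half_width
  vmax_b <- center + half_width
  n_resp <- floor(config$responsive_fraction * n)
  resp_idx <- sample.int(n, n_resp)
  direction <- rep("N", n)
  direction[resp_idx] <- rep_len(c("T", "S"), n_resp)[sample.int(n_resp)]
  scale <- 1 + stats::runif(n, 0.3, 1.5)
  fac <- ifelse(direction == "T", scale, ifelse(direction == "S", 1 / scale, 1))
  vmin_a <- vmin_b * fac
  vmax_a <- vmax_b * fac
  mk <- function(vmin, vmax, acc) {
    out <- data.frame(reaction_id = rid, vmin = pmin(vmin, vmax),
                      vmax = pmax(vmin, vmax), accession = acc,
                      stringsAsFactors = FALSE)
    class(out) <- c("flux_bounds", "data.frame")
    out
  }
  list(bounds_a = mk(vmin_a, vmax_a, "A"), bounds_b = mk(vmin_b, vmax_b, "B"),
       truth = data.frame(reaction_id = rid, direction = direction,
                          stringsAsFactors = FALSE))
}
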