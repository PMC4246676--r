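# Tiny models built in code for the LP tests.

mk_reaction <- function(id, st, lb = 0, ub = 1000, pathway = "core",
                        compartment = "c", genes = character(0),
                        exchange = FALSE) {
  list(id = id, name = id, stoichiometry = st, lower_bound = lb,
       upper_bound = ub, pathway = pathway, compartment = compartment,
       genes = genes, exchange = exchange)
}

mk_model <- function(reactions, objective) {
  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  mets <- data.frame(id = met_ids, name = met_ids,
                     compartment = sub(".*_", "", met_ids),
                     stringsAsFactors = FALSE)
  stoich_model(mets, lapply(reactions, fluxcord:::.as_reaction), objective)
}

# A -> B -> biomass, uptake capped at 10
chain_model <- function() {
  mk_model(list(
    mk_reaction("EX_A", c(A_c = 1), ub = 10, exchange = TRUE),
    mk_reaction("R_AB", c(A_c = -1, B_c = 1)),
    mk_reaction("BIO", c(B_c = -1), exchange = TRUE)), "BIO")
}

# A -> B via two equivalent parallel branches
parallel_model <- function() {
  mk_model(list(
    mk_reaction("EX_A", c(A_c = 1), ub = 10, exchange = TRUE),
    mk_reaction("R1", c(A_c = -1, B_c = 1)),
    mk_reaction("R2", c(A_c = -1, B_c = 1)),
    mk_reaction("BIO", c(B_c = -1), exchange = TRUE)), "BIO")
}

# uptake splits into a branch feeding biomass and a vented side branch
branched_model <- function() {
  mk_model(list(
    mk_reaction("EX_A", c(A_c = 1), ub = 10, exchange = TRUE),
    mk_reaction("R_MAIN", c(A_c = -1, B_c = 1)),
    mk_reaction("R_BRANCH", c(A_c = -1, C_c = 1)),
    mk_reaction("EX_C", c(C_c = -1), exchange = TRUE),
    mk_reaction("BIO", c(B_c = -1), exchange = TRUE)), "BIO")
}
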