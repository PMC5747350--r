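#' The packaged cholesterol-regulation prior-knowledge network
#'
#' The curated model of cellular cholesterol regulation: 21 protein nodes
#' (the SREBP precursor/SREBP1/SREBP2 transcription-factor module, LXR, the
#' cholesterol synthesis enzymes, LDLR/NPC1 uptake machinery, lipogenic and
#' efflux targets), two enzymatic-activity nodes (ACAT2, HMGCS1), 11
#' metabolite species (the acetyl-CoA-to-mevalonate synthesis intermediates,
#' cholesterol split into ER and medium pools, and the intracellular drugs
#' and drug metabolites), plus clamped inputs for drug doses, lipoprotein
#' starvation (LPDS) and five siRNA knockdowns - 44 interaction edges in
#' total, 25 nodes measured.
#'
#' Structural choices mirror the study design: SREBP activates SREBP1 and
#' SREBP2 through fixed edges; a hypothetical inhibitory edge runs from
#' SREBP1 back to SREBP (the simplest interaction explaining SREBP2
#' complementation under SREBP1 knockdown); ER cholesterol and
#' 25-hydroxycholesterol inhibit SREBP conjunctively; the five printed
#' metabolic rate laws (acetyl-CoA source 0.5*k1, ACAT2-mediated
#' condensation k2, HMGCS1-mediated synthesis k3, HMGCR Michaelis-Menten
#' flux with competitive atorvastatin inhibition k4/kM4/kI, mevalonate flux
#' k5, LDLR/NPC1-dependent uptake k6, drains k7/k8) are carried by the
#' metabolic edges; CholER, CholMedia, LDLR and NPC1 are unmeasured.
#'
#' @return A `pkn` object with 44 edges.
#' @export
cholesterol_pkn <- function() {
  prot <- function(id, measured = TRUE)
    network_nodes(id, category = "protein", measured = measured)
  met_in <- function(id, species = id, measured = TRUE, init = 0.5,
                     source_param = NA_character_, source_scale = 1)
    network_nodes(id, category = "metabolite_intracellular", species = species,
                  measured = measured, initial_level = init,
                  source_param = source_param, source_scale = source_scale)
  drug_in <- function(id, species, measured = TRUE)
    network_nodes(id, category = "drug_intracellular", species = species,
                  measured = measured, initial_level = 0)
  inp <- function(id, category)
    network_nodes(id, category = category, initial_level = 0)

  nodes <- rbind(
    prot("SREBP", measured = FALSE),
    prot(c("SREBP1", "SREBP2", "LXR", "HMGCR", "HMGCS1", "ACAT2")),
    prot("LDLR", measured = FALSE), prot("NPC1", measured = FALSE),
    prot(c("INSIG1", "SQLE", "LSS", "IDI1", "MVD", "DHCR7", "DHCR24",
           "FDFT1", "MSMO1", "FASN", "ELOVL6", "ABCA1")),
    network_nodes(c("ACAT2act", "HMGCS1act"), category = "activity"),
    met_in("AcetylCoA", source_param = "k1", source_scale = 0.5),
    met_in("AcetoacetylCoA"),
    met_in("HMGCoA"),
    met_in("Mevalonate"),
    met_in("CholER", species = "Cholesterol", measured = FALSE),
    network_nodes("CholMedia", category = "metabolite_extracellular",
                  species = "Cholesterol", measured = FALSE),
    drug_in("AtorvaIn", "Atorvastatin"),
    drug_in("T09In", "T0901317"),
    drug_in("GWIn", "GW3965"),
    drug_in("OHAtorva", "HydroxyAtorvastatin", measured = FALSE),
    drug_in("AtorvaLactone", "AtorvastatinLactone", measured = FALSE),
    drug_in("OHGW", "HydroxyGW3965", measured = FALSE),
    inp(c("AtorvaEx", "T09Ex", "GWEx", "HC25"), "drug_extracellular"),
    inp("LPDS", "stimulus"),
    inp(c("siSREBF1", "siSREBF2", "siLDLR", "siNPC1", "siHMGCS1"),
        "knockdown_input")
  )

  hill <- function(src, tgt, sign = 1, id = paste0(src, "_", tgt), ...) {
    network_edge(id, data.frame(node = src, sign = sign, exponent = 1),
                 tgt, mechanism = "hill_regulatory", ...)
  }
  si <- function(kd, tgt) hill(kd, tgt, sign = -1, fixed = TRUE,
                               fixed_k = 0.5, fixed_n = 4)

  edges <- c(
    list(
      # sterol sensing: ER cholesterol, the hypothetical SREBP1 feedback and
      # 25-hydroxycholesterol jointly gate SREBP activation (AND of NOTs)
      network_edge("sterol_SREBP",
                   data.frame(node = c("CholER", "SREBP1", "HC25"),
                              sign = -1, exponent = 1),
                   "SREBP", mechanism = "hill_regulatory"),
      hill("SREBP", "SREBP1", fixed = TRUE, fixed_k = 0.5, fixed_n = 2),
      hill("SREBP", "SREBP2", fixed = TRUE, fixed_k = 0.5, fixed_n = 2),
      hill("T09In", "LXR"), hill("GWIn", "LXR"),
      hill("ACAT2", "ACAT2act"), hill("HMGCS1", "HMGCS1act")
    ),
    lapply(c("HMGCR", "HMGCS1", "ACAT2", "LDLR", "NPC1", "INSIG1", "SQLE",
             "LSS", "IDI1", "MVD", "DHCR7", "DHCR24", "FDFT1", "MSMO1"),
           function(t) hill("SREBP2", t)),
    list(
      hill("LXR", "ABCA1"), hill("LXR", "SREBP1"),
      hill("SREBP1", "FASN"), hill("SREBP1", "ELOVL6"),
      hill("LPDS", "CholMedia", sign = -1),
      si("siSREBF1", "SREBP1"), si("siSREBF2", "SREBP2"),
      si("siLDLR", "LDLR"), si("siNPC1", "NPC1"), si("siHMGCS1", "HMGCS1"),
      # drug uptake and metabolism (bounded saturating dose-response)
      hill("AtorvaEx", "AtorvaIn"), hill("T09Ex", "T09In"),
      hill("GWEx", "GWIn"), hill("AtorvaIn", "OHAtorva"),
      hill("AtorvaIn", "AtorvaLactone"), hill("GWIn", "OHGW"),
      # metabolic reactions (explicit rate laws)
      network_edge("e_k2",
                   data.frame(node = c("ACAT2act", "AcetylCoA"), sign = 1,
                              exponent = c(1, 2)),
                   "AcetoacetylCoA", mechanism = "mass_action",
                   rate_param = "k2", consumes = "AcetylCoA"),
      network_edge("e_k3",
                   data.frame(node = c("HMGCS1act", "AcetylCoA",
                                       "AcetoacetylCoA"), sign = 1,
                              exponent = 1),
                   "HMGCoA", mechanism = "mass_action", rate_param = "k3",
                   consumes = c("AcetylCoA", "AcetoacetylCoA")),
      network_edge("e_k4",
                   data.frame(node = c("HMGCR", "HMGCoA", "AtorvaIn"),
                              sign = c(1, 1, -1), exponent = 1),
                   "Mevalonate", mechanism = "michaelis_menten_inhibited",
                   rate_param = "k4", km_param = "kM4", ki_param = "kI",
                   substrate = "HMGCoA", consumes = "HMGCoA"),
      network_edge("e_k5", data.frame(node = "Mevalonate", sign = 1,
                                      exponent = 1),
                   "CholER", mechanism = "mass_action", rate_param = "k5",
                   consumes = "Mevalonate"),
      network_edge("e_k6",
                   data.frame(node = c("CholMedia", "LDLR", "NPC1"), sign = 1,
                              exponent = 1),
                   "CholER", mechanism = "uptake_product", rate_param = "k6"),
      network_edge("e_k7", data.frame(node = "AcetylCoA", sign = -1,
                                      exponent = 1),
                   "AcetylCoA", mechanism = "mass_action", rate_param = "k7"),
      network_edge("e_k8", data.frame(node = "CholER", sign = -1,
                                      exponent = 1),
                   "CholER", mechanism = "mass_action", rate_param = "k8")
    )
  )
  pkn(nodes, edges, name = "cholesterol_regulation")
}

#' The reduced toy network for fast fitting experiments
#'
#' An 8-node miniature with the same hybrid structure as the full model: a
#' stimulus-driven transcription factor with two protein targets, and a
#' three-metabolite chain (source/drain M1, condensation to M2, and an
#' inhibited Michaelis-Menten step to M3 whose inhibitor is a clamped drug
#' input). Six nodes are measured. Fitting runs on it in seconds, so it backs
#' the parameter-recovery and optimizer property tests.
#'
#' @return A `pkn` object.
#' @export
toy_pkn <- function() {
  nodes <- rbind(
    network_nodes("S", category = "stimulus", initial_level = 0),
    network_nodes("D", category = "drug_extracellular", initial_level = 0),
    network_nodes(c("TF", "P1", "P2"), category = "protein", measured = TRUE),
    network_nodes("M1", category = "metabolite_intracellular", species = "M1",
                  measured = TRUE, source_param = "k1"),
    network_nodes(c("M2", "M3"), category = "metabolite_intracellular",
                  species = c("M2", "M3"), measured = TRUE)
  )
  hill <- function(src, tgt) network_edge(
    paste0(src, "_", tgt), data.frame(node = src, sign = 1, exponent = 1),
    tgt, mechanism = "hill_regulatory")
  edges <- list(
    hill("S", "TF"), hill("TF", "P1"), hill("TF", "P2"),
    network_edge("e_m1drain", data.frame(node = "M1", sign = -1, exponent = 1),
                 "M1", mechanism = "mass_action", rate_param = "k3"),
    network_edge("e_m2", data.frame(node = c("P1", "M1"), sign = 1,
                                    exponent = 1),
                 "M2", mechanism = "mass_action", rate_param = "k2",
                 consumes = "M1"),
    network_edge("e_m3", data.frame(node = c("P2", "M2", "D"),
                                    sign = c(1, 1, -1), exponent = 1),
                 "M3", mechanism = "michaelis_menten_inhibited",
                 rate_param = "k4", km_param = "kM4", ki_param = "kI",
                 substrate = "M2", consumes = "M2"),
    network_edge("e_m3drain", data.frame(node = "M3", sign = -1, exponent = 1),
                 "M3", mechanism = "mass_action", rate_param = "k5")
  )
  pkn(nodes, edges, name = "toy")
}

#' The 23-condition perturbation design
#'
#' The modeled condition roster: two doses each of atorvastatin, T0901317,
#' GW3965 and 25-hydroxycholesterol, lipoprotein-deficient serum (LPDS)
#' alone and with atorvastatin at two doses, two independent siRNAs each
#' against SREBF1, SREBF2, LDLR, NPC1 and HMGCS1, the combined SREBF1+2
#' knockdown, and the untreated reference - 23 conditions. Drug doses map to
#' scaled input levels (low dose 0.5, high dose 1); siRNA efficiencies are
#' 0.8 and 0.7 for the two independent siRNAs. Drug-class conditions run to
#' the 48-h-class horizon (100 time units), siRNA conditions to the
#' 72-h-class horizon (150).
#'
#' @return Data frame with columns `condition`, `class`, `end_time`,
#'   `untreated` and one column per clamped input node.
#' @export
default_conditions <- function() {
  inputs <- c("AtorvaEx", "T09Ex", "GWEx", "HC25", "LPDS", "siSREBF1",
              "siSREBF2", "siLDLR", "siNPC1", "siHMGCS1")
  base <- stats::setNames(rep(0, length(inputs)), inputs)
  row <- function(condition, class, ...) {
    lv <- base
    set <- c(...)
    lv[names(set)] <- set
    cbind(data.frame(condition = condition, class = class,
                     end_time = if (class == "sirna72") 150 else 100,
                     untreated = condition == "untreated",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(lv)))
  }
  rbind(
    row("untreated", "drug48"),
    row("atorva_low", "drug48", c(AtorvaEx = 0.5)),
    row("atorva_high", "drug48", c(AtorvaEx = 1)),
    row("t09_low", "drug48", c(T09Ex = 0.5)),
    row("t09_high", "drug48", c(T09Ex = 1)),
    row("gw_low", "drug48", c(GWEx = 0.5)),
    row("gw_high", "drug48", c(GWEx = 1)),
    row("hc25_low", "drug48", c(HC25 = 0.5)),
    row("hc25_high", "drug48", c(HC25 = 1)),
    row("lpds", "drug48", c(LPDS = 1)),
    row("lpds_atorva_low", "drug48", c(LPDS = 1, AtorvaEx = 0.5)),
    row("lpds_atorva_high", "drug48", c(LPDS = 1, AtorvaEx = 1)),
    row("si_srebf1_a", "sirna72", c(siSREBF1 = 0.8)),
    row("si_srebf1_b", "sirna72", c(siSREBF1 = 0.7)),
    row("si_srebf2_a", "sirna72", c(siSREBF2 = 0.8)),
    row("si_srebf2_b", "sirna72", c(siSREBF2 = 0.7)),
    row("si_ldlr_a", "sirna72", c(siLDLR = 0.8)),
    row("si_ldlr_b", "sirna72", c(siLDLR = 0.7)),
    row("si_npc1_a", "sirna72", c(siNPC1 = 0.8)),
    row("si_npc1_b", "sirna72", c(siNPC1 = 0.7)),
    row("si_hmgcs1_a", "sirna72", c(siHMGCS1 = 0.8)),
    row("si_hmgcs1_b", "sirna72", c(siHMGCS1 = 0.7)),
    row("si_srebf12", "sirna72", c(siSREBF1 = 0.8, siSREBF2 = 0.8))
  )
}

#' Condition roster for the toy network
#'
#' Six conditions spanning the stimulus and inhibitor design of [toy_pkn()].
#'
#' @return Data frame in the same layout as [default_conditions()].
#' @export
toy_conditions <- function() {
  # the toy relaxes within a few time constants; a 40-unit horizon keeps
  # fitting runs fast while still reaching quasi-steady state
  row <- function(condition, S, D, untreated = FALSE) {
    data.frame(condition = condition, class = "drug48", end_time = 40,
               untreated = untreated, S = S, D = D, stringsAsFactors = FALSE)
  }
  rbind(
    row("untreated", 0.5, 0, untreated = TRUE),
    row("stim_off", 0, 0),
    row("stim_high", 1, 0),
    row("inhibitor", 0.5, 1),
    row("stim_high_inhibitor", 1, 1),
    row("inhibitor_low", 0.5, 0.5)
  )
}

#' Paths to the packaged network fixture files
#'
#' The cholesterol network ships as a SIF file plus a metadata CSV under the
#' package's `extdata` directory; [read_network()] on this pair reproduces
#' [cholesterol_pkn()].
#'
#' @return Named character vector with elements `sif` and `metadata`.
#' @export
cholesterol_pkn_files <- function() {
  c(sif = system.file("extdata", "cholesterol_pkn.sif", package = "cholode",
                      mustWork = TRUE),
    metadata = system.file("extdata", "cholesterol_pkn_metadata.csv",
                           package = "cholode", mustWork = TRUE))
}
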