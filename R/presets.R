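# Preset networks emulating the four focal waterfowl quartets plus a
# 24-waterfowl + chicken backbone. Internal branch lengths (and, where a
# preset carries gene flow, the pulse proportion gamma) are tuned
# analytically so that the expected fractions of the two discordant
# genealogy classes match the genome-wide levels each quartet is meant to
# emulate; see the methods vignette for the closed forms used.

# Expected class fractions for a quartet with one pulse from donor P3 into
# a recipient sister-pair lineage: with probability gamma the recipient
# lineage rides the donor branch for (t_anc - tau) units and pairs with P3
# unless it escapes (prob E = exp(-(t_anc - tau))); escaped or unmoved
# lineages follow the standard MSC law with internal branch t.
quartet_class_expectation <- function(t, gamma = 0, tau = 0.3, t12 = 1,
                                      recipient = c("P1", "P2")) {
  recipient <- match.arg(recipient)
  E <- exp(-(t12 + t - tau))
  ils_minor <- (1 / 3) * exp(-t)
  v_intro <- gamma * ((1 - E) + E / 3)
  v_other <- gamma * E / 3
  base <- (1 - gamma) * ils_minor
  if (recipient == "P1") {
    v2 <- v_intro + base
    v3 <- v_other + base
  } else {
    v3 <- v_intro + base
    v2 <- v_other + base
  }
  c(v0_v1 = 1 - v2 - v3, v2 = v2, v3 = v3)
}

#' Preset species networks emulating the waterfowl study system
#'
#' Returns ready-made [species_network()] objects for the four focal
#' quartets (screamer/magpie-goose/whistling-duck, shelduck/perching-duck,
#' steamer-duck/shoveler, and the mallard complex) and a 25-leaf backbone
#' (24 waterfowl + chicken outgroup). Quartet internal branch lengths are
#' tuned so that the expected discordant fraction V2+V3 approximates the
#' genome-wide ILS level each quartet emulates (56.8, 31, 69.4 and 59
#' percent respectively); `screamer_magpie`, `steamer_shoveler` and
#' `mallard_complex` carry an introgression pulse reproducing the V2/V3
#' asymmetry expected for those nodes.
#'
#' @param name One of `"screamer_magpie"`, `"shelduck_perching"`,
#'   `"steamer_shoveler"`, `"mallard_complex"`, `"full24"`.
#' @param gamma Optional override of the preset's admixture proportion
#'   (e.g. `gamma = 0` for a pure-ILS variant); ignored for `full24`.
#' @param scale Substitutions/site per coalescent unit (default 0.01).
#' @return A `species_network`. The design target for the expected ILS
#'   percentage is attached as attribute `"design_ils_percent"` for the
#'   quartet presets.
#' @examples
#' nw <- waterfowl_preset("mallard_complex")
#' attr(nw, "design_ils_percent")
#' @export
waterfowl_preset <- function(name = c("screamer_magpie", "shelduck_perching",
                                      "steamer_shoveler", "mallard_complex",
                                      "full24"),
                             gamma = NULL, scale = 0.01) {
  name <- match.arg(name)
  if (name == "full24") return(full24_network(scale))

  cfg <- switch(
    name,
    screamer_magpie = list(
      taxa = c("Anseranas_semipalmata", "Dendrocygna_arborea",
               "Chauna_torquata", "Gallus_gallus"),
      t = 0.952, gamma = 0.458, recipient = "P1", target = 56.8
    ),
    shelduck_perching = list(
      taxa = c("Cairina_moschata", "Anas_platyrhynchos",
               "Tadorna_radjah", "Gallus_gallus"),
      t = 0.7657, gamma = 0, recipient = "P1", target = 31
    ),
    steamer_shoveler = list(
      taxa = c("Spatula_rhynchotis", "Anas_platyrhynchos",
               "Tachyeres_pteneres", "Gallus_gallus"),
      t = 0.03, gamma = 0.2445, recipient = "P1", target = 69.4
    ),
    mallard_complex = list(
      taxa = c("Anas_platyrhynchos", "Anas_zonorhyncha",
               "Anas_superciliosa", "Gallus_gallus"),
      t = 0.146, gamma = 0.05, recipient = "P2", target = 59
    )
  )
  g <- gamma %||% cfg$gamma
  events <- NULL
  if (g > 0) {
    rec_taxon <- cfg$taxa[match(cfg$recipient, c("P1", "P2"))]
    events <- tibble::tibble(
      recipient = rec_taxon, donor = cfg$taxa[3], time = 0.3, gamma = g
    )
  }
  nw <- quartet_network(cfg$t, t12 = 1, t_out = 5, taxa = cfg$taxa,
                        scale = scale, events = events)
  attr(nw, "design_ils_percent") <- cfg$target
  attr(nw, "preset") <- name
  nw
}

# Build an ultrametric newick from a nested (age, left, right) structure.
chrono_newick <- function(node, parent_age) {
  if (is.character(node)) {
    return(sprintf("%s:%.10g", node, parent_age))
  }
  sprintf("(%s,%s):%.10g",
          chrono_newick(node$l, node$age),
          chrono_newick(node$r, node$age),
          parent_age - node$age)
}

cl <- function(age, l, r) list(age = age, l = l, r = r)

full24_network <- function(scale = 0.01) {
  # 24 waterfowl + chicken; ages in coalescent units. The three focal
  # internal branches reuse the quartet presets' tuned lengths.
  mallards <- cl(0.25, "Anas_superciliosa",
                 cl(0.104, "Anas_platyrhynchos", "Anas_zonorhyncha"))
  anas_side <- cl(0.35, "Mareca_strepera", mallards)
  spatulas <- cl(0.25, "Spatula_rhynchotis", "Spatula_clypeata")
  dabbling <- cl(0.45, "Tachyeres_pteneres", cl(0.42, spatulas, anas_side))
  diving <- cl(0.30, "Aythya_fuligula", "Netta_rufina")
  core_ducks <- cl(0.50, diving, dabbling)
  perching <- cl(0.30, "Cairina_moschata", "Aix_galericulata")
  duck_crown <- cl(0.5343, perching, core_ducks)
  ducks <- cl(1.30, "Tadorna_radjah", duck_crown)
  swans <- cl(0.40, "Cygnus_atratus", "Cygnus_olor")
  geese <- cl(0.50, "Anser_cygnoides", "Branta_canadensis")
  geese_swans <- cl(1.20, cl(0.70, "Coscoroba_coscoroba",
                             "Cereopsis_novaehollandiae"),
                    cl(0.90, swans, geese))
  anatinae <- cl(1.45, geese_swans, ducks)
  anatidae <- cl(1.60, "Oxyura_jamaicensis", anatinae)
  anatidae2 <- cl(1.80, cl(0.50, "Dendrocygna_arborea",
                           "Dendrocygna_javanica"), anatidae)
  magpie_clade <- cl(2.048, "Anseranas_semipalmata", anatidae2)
  screamers <- cl(1.20, "Chauna_torquata", "Anhima_cornuta")
  waterfowl <- cl(3.0, screamers, magpie_clade)
  root <- cl(12, "Gallus_gallus", waterfowl)
  nwk <- paste0(sprintf("(%s,%s);", chrono_newick(root$l, root$age),
                        chrono_newick(root$r, root$age)))
  nw <- species_network(nwk, scale = scale, outgroup = "Gallus_gallus")

  # Per-branch mutation scales emulate lineage-specific effective
  # population sizes: mutation-unit branch durations are comparable across
  # branches (lognormal around 0.004 subs/site) while coalescent-unit
  # durations vary, so theta = mut_len / coal_len varies across nodes and
  # tracks the branch's ILS propensity, as in real phylogenomic data.
  ntip <- length(nw$tree$tip.label)
  nodes <- seq_len(ntip + nw$tree$Nnode)
  nonroot <- nodes[nodes != nw$root]
  coal_len <- nw$ages[nw$parent_of[nonroot]] - nw$ages[nonroot]
  mut_target <- with_seed(
    424242L, 0.004 * exp(stats::rnorm(length(nonroot), 0, 0.25))
  )
  s_b <- pmin(pmax(mut_target / coal_len, 5e-4), 0.05)
  names(s_b) <- nw$node_names[nonroot]
  nw <- species_network(nw$tree, scale = scale, outgroup = "Gallus_gallus",
                        branch_scale = s_b)
  attr(nw, "preset") <- "full24"
  nw
}
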