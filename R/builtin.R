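#' Built-in trait rulebook for WOR-3-style metabolic reconstruction
#'
#' Encodes the diagnostic-gene criteria used to reconstruct carbon, sulfur,
#' nitrogen, energy-conservation and hydrogen metabolism across MAG
#' collections: pathway presence requires co-annotation of the listed
#' diagnostic genes (never a single marker, except for the traits that are
#' themselves single-enzyme capabilities such as `adh` or `nosZ`), and
#' multi-subunit complexes require strictly more than half of their core
#' subunits.
#'
#' KO identifier lists are best-effort defaults matched alongside (never
#' instead of) gene symbols; edit them by saving the rulebook with
#' [save_rulebook()] and reloading a modified copy.
#'
#' @param nuo_subunits Core subunit symbols for respiratory complex I. The
#'   default is the 11 membrane/core subunits NuoA-NuoN excluding the
#'   NuoE/F/G input module, which is frequently absent or fused in draft
#'   genomes; override to taste.
#' @param vatpase_subunits Core subunit symbols for the V/A-type ATP
#'   synthase; the default covers the A, B, C, D, E, F, I and K subunits.
#' @return A validated `mag_rulebook`.
#' @export
#' @examples
#' rb <- builtin_rulebook()
#' rb$rules$asr$requirement$kind  # "all_of"
builtin_rulebook <- function(nuo_subunits = paste0("nuo", c("A", "B", "C", "D", "H", "I", "J", "K", "L", "M", "N")),
                             vatpase_subunits = paste0("ntp", c("A", "B", "C", "D", "E", "F", "I", "K"))) {
  g <- gene_spec
  cx <- complex_spec

  nuo_kos <- c(nuoA = "K00330", nuoB = "K00331", nuoC = "K00332", nuoD = "K00333",
               nuoH = "K00337", nuoI = "K00338", nuoJ = "K00339", nuoK = "K00340",
               nuoL = "K00341", nuoM = "K00342", nuoN = "K00343")
  ntp_kos <- c(ntpA = "K02117", ntpB = "K02118", ntpC = "K02119", ntpD = "K02120",
               ntpE = "K02121", ntpF = "K02122", ntpI = "K02123", ntpK = "K02124")

  nuo_specs <- lapply(nuo_subunits, function(s)
    g(s, ko_ids = unname(nuo_kos[s])[!is.na(nuo_kos[s])]))
  ntp_specs <- lapply(vatpase_subunits, function(s)
    g(s, ko_ids = unname(ntp_kos[s])[!is.na(ntp_kos[s])]))

  complex_i <- cx("nuo", nuo_specs)
  complex_ii <- cx("sdhABCD", list(g("sdhA", "K00239"), g("sdhB", "K00240"),
                                   g("sdhC", "K00241"), g("sdhD", "K00242")))
  complex_iv_aa3 <- cx("coxABC", list(g("coxA", "K02274"), g("coxB", "K02275"),
                                      g("coxC", "K02276")))
  complex_iv_bd <- cx("cydAB", list(g("cydA", "K00425"), g("cydB", "K00426")))
  kor <- cx("korABCD", list(g("korA", "K00174"), g("korB", "K00175"),
                            g("korC", "K00176"), g("korD", "K00177")))

  rules <- list(
    ## --- carbon metabolism --------------------------------------------------
    trait_rule("glycolysis", "Glycolysis (EMP, via rate-limiting enzymes)",
      "carbon metabolism",
      all_of(g("glk", "K00845"), g("pfk", "K00850"), g("ppdk", "K01006")),
      notes = "Rate-limiting enzymes glucokinase, 6-phosphofructokinase and pyruvate/orthophosphate dikinase must all be annotated."),
    trait_rule("gluconeogenesis", "Gluconeogenesis (irreversible-step enzymes)",
      "carbon metabolism",
      all_of(any_of(g("pckG", "K01596"), g("pckA", "K01610")),
             g("fbp", "K03841"), g("gapA", "K00134")),
      notes = "PEP carboxykinase accepted in either its GTP-dependent (pckG) or ATP-dependent (pckA) form, plus fructose-1,6-bisphosphatase and GAPDH."),
    trait_rule("tca_cycle", "TCA cycle (rate-limiting enzymes)",
      "carbon metabolism",
      all_of(g("cs", "K01647"), g("idh", "K00031"), kor),
      notes = "Citrate synthase, isocitrate dehydrogenase (any isoform symbolised idh/IDH) and the 2-oxoglutarate:ferredoxin oxidoreductase complex."),
    trait_rule("ppp_oxidative", "Pentose phosphate pathway, oxidative phase",
      "carbon metabolism",
      all_of(g("zwf", "K00036"), g("pgl", "K01057"), g("gnd", "K00033")),
      notes = "Glucose-6-phosphate 1-dehydrogenase, 6-phosphogluconolactonase, 6-phosphogluconate dehydrogenase."),
    trait_rule("ppp_nonoxidative", "Pentose phosphate pathway, non-oxidative phase",
      "carbon metabolism",
      all_of(g("tkt", "K00615"), g("tal", "K00616")),
      notes = "Transketolase and transaldolase."),
    trait_rule("ethanol_utilization", "Ethanol oxidation (alcohol dehydrogenase)",
      "carbon metabolism",
      g("adh", "K00001"),
      notes = "Single-marker trait by design: the capability is the enzyme itself."),
    trait_rule("formate_oxidation", "Formate oxidation (formate dehydrogenase)",
      "carbon metabolism",
      g("fdh", c("K00122", "K22516")),
      notes = "Single-marker trait: formate dehydrogenase."),
    trait_rule("co_oxidation", "CO oxidation (CO dehydrogenase)",
      "carbon metabolism",
      all_of(g("coxL", "K03520"), any_of(g("coxS", "K03518"), g("coxM", "K03519"))),
      notes = "The catalytic large subunit is mandatory; the small or medium subunit corroborates."),
    trait_rule("xylose_utilization", "Xylose utilisation (xylose isomerase)",
      "carbon metabolism",
      g("xylA", "K01805"),
      notes = "Single-marker trait: xylose isomerase feeds xylose into glycolysis."),
    ## --- fatty acid metabolism ----------------------------------------------
    trait_rule("beta_oxidation", "Fatty acid beta-oxidation (complete spiral)",
      "fatty acid metabolism",
      all_of(g("fadD", "K01897"), g("acd", "K00249"), g("crt", "K01692"),
             g("hbd", "K00074"), g("fadA", "K00632")),
      notes = "Acyl-CoA synthetase, acyl-CoA dehydrogenase, enoyl-CoA hydratase, 3-hydroxyacyl-CoA dehydrogenase and acetyl-CoA acyltransferase."),
    ## --- carbon fixation -----------------------------------------------------
    trait_rule("cbb_cycle", "CBB cycle carbon fixation (RuBisCO + PRK)",
      "carbon fixation",
      all_of(any_of(g("rbcL", "K01601"), g("rbcS", "K01602")), g("prk", "K00855")),
      notes = "Either RuBisCO subunit gene plus phosphoribulokinase; rbcL alone (form III enzymes lack rbcS) is accepted."),
    trait_rule("rtca_cycle", "rTCA cycle carbon fixation",
      "carbon fixation",
      all_of(g("gltA", "K01647"),
             cx("frdABCD", list(g("frdA", "K00244"), g("frdB", "K00245"),
                                g("frdC", "K00246"), g("frdD", "K00247"))),
             kor),
      notes = "Citrate synthase (gltA), fumarate reductase complex and 2-oxoglutarate:ferredoxin oxidoreductase complex."),
    ## --- sulfur metabolism ---------------------------------------------------
    trait_rule("sulfhydrogenase", "Sulfhydrogenase (HydABDG)",
      "sulfur metabolism",
      cx("hydABDG", list(g("hydA", "K17993"), g("hydB", "K17994"),
                         g("hydD", "K17995"), g("hydG", "K17996"))),
      notes = "Four-subunit sulfhydrogenase; more than half the subunits required."),
    trait_rule("asr", "Assimilatory sulfate reduction (sulfate to sulfite)",
      "sulfur metabolism",
      all_of(g("sat", "K00958"), g("cysC", "K00860"), g("cysH", "K00390")),
      notes = "All three enzymes (sulfate adenylyltransferase, adenylylsulfate kinase, PAPS reductase) must co-occur."),
    trait_rule("sulfite_reduction", "Sulfite reduction (sulfite to sulfide)",
      "sulfur metabolism",
      any_of(cx("cysJI", list(g("cysJ", "K00380"), g("cysI", "K00381"))),
             g("sir", "K00392")),
      notes = "Either the NADPH-dependent CysJI flavoprotein complex or ferredoxin-dependent Sir."),
    trait_rule("cysteine_synthesis", "Cysteine synthesis from sulfide",
      "sulfur metabolism",
      g("cysK", "K01738"),
      notes = "Single-marker trait: cysteine synthase."),
    ## --- nitrogen metabolism -------------------------------------------------
    trait_rule("dnr", "Dissimilatory nitrate reduction (NarGHI)",
      "nitrogen metabolism",
      cx("narGHI", list(g("narG", "K00370"), g("narH", "K00371"),
                        g("narI", "K00374"))),
      notes = "Membrane-bound respiratory nitrate reductase; more than half of the three subunits, i.e. at least two."),
    trait_rule("n2o_reduction", "Nitrous oxide reduction (NosZ)",
      "nitrogen metabolism",
      g("nosZ", "K00376"),
      notes = "Single-marker trait: nitrous-oxide reductase."),
    ## --- energy conservation -------------------------------------------------
    trait_rule("complex_i", "Respiratory complex I (NADH dehydrogenase, nuo)",
      "energy conservation", complex_i,
      notes = "Configurable core subunit set; default NuoA-N minus the E/F/G module."),
    trait_rule("complex_ii", "Respiratory complex II (succinate dehydrogenase)",
      "energy conservation", complex_ii),
    trait_rule("complex_iii", "Respiratory complex III (cytochrome b, petB)",
      "energy conservation", g("petB", "K00412"),
      notes = "Single-marker trait; deliberately excluded from the complete-chain call."),
    trait_rule("complex_iv_aa3", "Complex IV, aa3-type cytochrome c oxidase",
      "energy conservation", complex_iv_aa3),
    trait_rule("complex_iv_bd", "Complex IV, cytochrome bd ubiquinol oxidase",
      "energy conservation", complex_iv_bd),
    trait_rule("rnf_complex", "Rnf complex (Na+-translocating Fd:NAD+ oxidoreductase)",
      "energy conservation",
      cx("rnfABCDEG", list(g("rnfA", "K03617"), g("rnfB", "K03616"),
                           g("rnfC", "K03615"), g("rnfD", "K03614"),
                           g("rnfE", "K03613"), g("rnfG", "K03612"))),
      notes = "Six-subunit complex; hallmark of anaerobic energy conservation."),
    trait_rule("va_atpase", "V/A-type ATP synthase",
      "energy conservation", cx("va_atpase", ntp_specs),
      notes = "Configurable subunit inventory; default A,B,C,D,E,F,I,K."),
    trait_rule("respiratory_chain_complete", "Complete aerobic respiratory chain (I + II + IV)",
      "energy conservation",
      all_of(complex_i, complex_ii, any_of(complex_iv_aa3, complex_iv_bd)),
      notes = "Complex III is intentionally not required: its absence in otherwise aerobic genomes argues it is non-essential for the lifestyle call."),
    ## --- hydrogen metabolism -------------------------------------------------
    trait_rule("mvh_hdr", "MvhADG-HdrABC hydrogenase-heterodisulfide reductase",
      "electron transport and hydrogen metabolism",
      all_of(cx("mvhADG", list(g("mvhA", "K14126"), g("mvhD", "K14127"),
                               g("mvhG", "K14128"))),
             cx("hdrABC", list(g("hdrA", "K03388"), g("hdrB", "K03389"),
                               g("hdrC", "K03390")))),
      notes = "Both three-subunit modules must independently pass the >50% subunit threshold.")
  )

  rulebook(rules, version = "builtin-1.0")
}
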