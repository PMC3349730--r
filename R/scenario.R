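## Wild-type ARS consensus sequence (ACS) of the ARS1531 origin; the single
## T->C substitution at position 4 abolishes origin activity.
ACS_WT <- "ATATTTATATTTAGA"

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b DNA strings over the ACGT alphabet, equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("sequences must contain only A, C, G, T")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Is an ARS consensus sequence functional?
#'
#' Tests a 15-mer against the wild-type ACS; any deviation (e.g. the T->C
#' change at position 4) abolishes origin activity.
#'
#' @param seq A 15-letter DNA string.
#' @return `TRUE` iff `seq` equals the wild-type ACS.
#' @export
acs_is_functional <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) != nchar(ACS_WT))
    stop(sprintf("ACS must be %d letters", nchar(ACS_WT)))
  if (grepl("[^ACGT]", seq)) stop("ACS must contain only A, C, G, T")
  hamming_distance(seq, ACS_WT) == 0L
}

## -------------------------------------------------------------------------
## Scenario geometry (bp). The chromosome XIV coordinates are invented but
## encode the experiment's relative distances: the MET2 BglII site 8.5 kb
## left of ARS1410; the native centromere 6.8 kb left of ARS1426 and ~19 kb
## right of ARS1424; the relocated centromere 11.5 kb left of ARS1410.
CHR14_LENGTH <- 784000
POS_MET2     <- 441500
POS_ARS1410  <- 450000
POS_ARS1424  <- 609000
POS_CEN14    <- 628000
POS_ARS1426  <- 634800
POS_CEN_RELOC <- 438500

## Replication indices per scenario. Named chromosome XIV loci carry the
## measured slot-blot values; filler origins (invented ids) complete a
## realistic origin spacing so the whole genome finishes S phase and the
## genomic probe plateaus inside the 0-140 min window.
chr14_filler <- data.frame(
  id = sprintf("ori14_%03d", c(30, 80, 130, 185, 240, 300, 360, 410,
                               520, 560, 690, 740)),
  position = 1000 * c(30, 80, 130, 185, 240, 300, 360, 410,
                      520, 560, 690, 740),
  ri = c(0.40, 0.55, 0.30, 0.60, 0.35, 0.50, 0.30, 0.55,
         0.45, 0.50, 0.40, 0.45),
  stringsAsFactors = FALSE)

scenario_ri_table <- function(name) {
  named <- switch(name,
    wt = c(ARS1410 = 0.77, ARS1424 = 0.11, ARS1426 = 0.16,
           MET2 = 0.87, ARS1 = 0.68),
    rearranged = c(ARS1410 = 0.23, ARS1424 = 0.27, ARS1426 = 0.79,
                   MET2 = 0.24, ARS1 = 0.66),
    cen_dead = c(ARS1410 = 0.74, ARS1424 = 0.11, ARS1426 = 0.16,
                 MET2 = 0.81, ARS1 = 0.68))
  c(named, ARS306 = 0, R11 = 1)
}

## Population-median calibration: an origin with efficiency e and firing sd
## s has its locus median replication time at mean + s * qnorm(0.5 / e)
## (passive replication arrives later in our layouts), so the mean firing
## time is set that much earlier than the target.
firing_time_for_ri <- function(ri, early_trep, late_trep, params,
                               firing_sd, efficiency) {
  if (efficiency <= 0.5)
    stop("median calibration requires origin efficiency > 0.5")
  target <- early_trep + ri * (late_trep - early_trep) - params$s_entry_mean
  m <- target - firing_sd * stats::qnorm(0.5 / efficiency)
  if (m < 0) stop("calibrated firing time is negative; anchors too early")
  m
}

#' Build a fully parameterized density-transfer scenario
#'
#' Constructs the synthetic genome for one of the three chromosome XIV
#' strains: `"wt"` (native centromere 6.8 kb left of ARS1426),
#' `"rearranged"` (native centromere replaced, a functional centromere
#' integrated at MET2, 11.5 kb from ARS1410), or `"cen_dead"` (a
#' CDEIII-mutant, non-functional centromere at MET2 with the native
#' centromere retained). Besides the chromosome XIV-like chromosome the
#' genome carries a standards chromosome pair (early ARS306-role and late
#' R11-role loci), a control chromosome (ARS1 role), and a chromosome
#' XV-like chromosome whose ARS1531-role origin can be knocked out.
#'
#' Origin mean firing times are calibrated per scenario so that each named
#' locus's true population median replication time equals
#' `early_trep + RI * (late_trep - early_trep)` at its scenario's
#' replication index; the truth table is exposed in `true_ri`/`true_trep`.
#'
#' @param name One of `"wt"`, `"rearranged"`, `"cen_dead"`.
#' @param early_trep,late_trep Anchor T_reps (minutes) assigned to the
#'   early and late standards.
#' @param params A [sim_params()].
#' @param effect A [centromere_effect()]; carried for forward-model
#'   exploration (scenario firing times are already effective values).
#' @param firing_sd,efficiency Origin firing SD (minutes) and efficiency
#'   shared by all origins (efficiencies are deliberately equal across
#'   scenarios: centromere relocation does not alter origin efficiency).
#' @param ars1531_knockout If `TRUE`, the ARS1531-role origin's efficiency
#'   is set to 0 (a dead ACS), so its region is replicated passively and
#'   late.
#' @return An object of class `scenario`.
#' @export
build_scenario <- function(name = c("wt", "rearranged", "cen_dead"),
                           early_trep = 45, late_trep = 95,
                           params = sim_params(),
                           effect = centromere_effect(),
                           firing_sd = 4, efficiency = 0.85,
                           ars1531_knockout = FALSE) {
  if (!is.character(name) || !(name[1] %in% c("wt", "rearranged", "cen_dead")))
    stop("unknown scenario name: ", name[1])
  name <- match.arg(name)
  ris <- scenario_ri_table(name)
  mft <- function(ri) firing_time_for_ri(ri, early_trep, late_trep, params,
                                         firing_sd, efficiency)
  ori <- function(id, pos, ri, eff = efficiency)
    origin(id, pos, mft(ri), firing_sd = firing_sd, efficiency = eff)

  ors14 <- rbind(
    do.call(rbind, Map(ori, chr14_filler$id, chr14_filler$position,
                       chr14_filler$ri)),
    ori("ARS1410", POS_ARS1410, ris[["ARS1410"]]),
    ori("ARS1424", POS_ARS1424, ris[["ARS1424"]]),
    ori("ARS1426", POS_ARS1426, ris[["ARS1426"]]))
  ors14 <- ors14[order(ors14$position), ]
  cen14 <- switch(name,
    wt = centromere(POS_CEN14),
    rearranged = centromere(POS_CEN_RELOC),
    cen_dead = rbind(centromere(POS_CEN_RELOC, CDEIII_MUTANT),
                     centromere(POS_CEN14)))
  chr14 <- chromosome_model("chrXIV", CHR14_LENGTH, ors14, cen14)

  chr3 <- chromosome_model("chrIII", 170000, rbind(
    ori("ARS306", 40000, ris[["ARS306"]]),
    ori("ori03_120", 120000, 0.50)))
  chr5 <- chromosome_model("chrV", 140000, rbind(
    ori("ori05_030", 30000, 0.35),
    ori("R11", 100000, ris[["R11"]])))
  chr4 <- chromosome_model("chrIV", 100000, rbind(
    ori("ARS1", 50000, ris[["ARS1"]])))
  chr15 <- chromosome_model("chrXV", 220000, rbind(
    ori("ori15_040", 40000, 0.50),
    ori("ARS1531", 110000, 0.30,
        eff = if (ars1531_knockout) 0 else efficiency),
    ori("ori15_180", 180000, 0.45)))

  loci <- data.frame(
    locus = c("MET2", "ARS1410", "ARS1424", "ARS1426",
              "ARS306", "R11", "ARS1"),
    chrom = c(rep("chrXIV", 4), "chrIII", "chrV", "chrIV"),
    position = c(POS_MET2, POS_ARS1410, POS_ARS1424, POS_ARS1426,
                 40000, 100000, 50000),
    role = c("passive", "origin", "origin", "origin",
             "early_standard", "late_standard", "control"),
    stringsAsFactors = FALSE)
  true_ri <- ris[loci$locus]
  true_trep <- early_trep + true_ri * (late_trep - early_trep)

  structure(list(name = name,
                 chromosomes = list(chrXIV = chr14, chrIII = chr3,
                                    chrV = chr5, chrIV = chr4,
                                    chrXV = chr15),
                 loci = loci,
                 true_ri = true_ri, true_trep = true_trep,
                 anchors = c(early = early_trep, late = late_trep),
                 standards_ids = c(early = "ARS306", late = "R11"),
                 effect = effect, params = params,
                 firing_sd = firing_sd, efficiency = efficiency,
                 ars1531_knockout = ars1531_knockout),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> '%s': %d chromosomes, %d named loci%s\n",
              x$name, length(x$chromosomes), nrow(x$loci),
              if (x$ars1531_knockout) ", ARS1531 knocked out" else ""))
  tab <- data.frame(locus = x$loci$locus, chrom = x$loci$chrom,
                    position = x$loci$position,
                    true_ri = unname(x$true_ri),
                    true_trep = unname(x$true_trep))
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Truth table of a scenario
#'
#' @param scenario A [build_scenario()] result.
#' @return `data.frame` with columns `locus`, `chrom`, `position`,
#'   `true_trep`, `true_ri`.
#' @export
scenario_truth_table <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  data.frame(locus = scenario$loci$locus, chrom = scenario$loci$chrom,
             position = scenario$loci$position,
             true_trep = unname(scenario$true_trep),
             true_ri = unname(scenario$true_ri),
             stringsAsFactors = FALSE)
}
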