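# Carbon atom transition model: serine synthesis, pentose phosphate pathway,
# TCA cycle and nucleotide synthesis under a glucose tracer.
# 19 reactions, 21 metabolites. This reaction list is a reconstruction
# (see the package vignette for the assumptions behind every entry).
#
# Pools
SOURCE GLC 6
SOURCE SERX 3
SOURCE GLYX 2
SOURCE ASPX 4
SOURCE INS 10
SOURCE URD 9
SOURCE CO2 1
SINK MEETHF 1
#
# Biomass drains per unit growth rate (relative demands from dry-weight
# composition; overridable by editing this file)
BIOMASS SER 0.4
BIOMASS GLY 0.5
BIOMASS ASP 0.35
BIOMASS IMP 0.10
BIOMASS UMP 0.08
#
# Glycolysis and oxidative PPP. Upper-half carbons invert through DHAP.
HK: GLC (abcdef) -> G6P (abcdef)
PPPOX: G6P (abcdef) -> R5P (bcdef) + CO2 (a)
GLYC: G6P (abcdef) -> 3PG (cba) + 3PG (def)
#
# Serine synthesis pathway and serine/glycine one-carbon cleavage
SSP: 3PG (abc) -> SER (abc)
SERUP: SERX (abc) -> SER (abc)
SHMT: SER (abc) -> GLY (ab) + MEETHF (c)
GLYUP: GLYX (ab) -> GLY (ab)
#
# Lower glycolysis and TCA entry. PDH releases pyruvate C1 as CO2;
# pyruvate carboxylase fixes CO2 into OAA C4.
PK: 3PG (abc) -> PYR (abc)
PDH: PYR (abc) -> ACCOA (bc) + CO2 (a)
PC: PYR (abc) + CO2 (d) -> OAA (abcd)
#
# Lumped citrate synthase -> alpha-ketoglutarate (CO2 from OAA C1) and
# lumped AKG -> OAA with 50/50 succinate/fumarate scrambling.
CS: OAA (abcd) + ACCOA (ef) -> AKG (dcbfe) + CO2 (a)
TCA2[0.5]: AKG (abcde) -> OAA (bcde) + CO2 (a)
TCA2[0.5]: AKG (abcde) -> OAA (edcb) + CO2 (a)
#
# Aspartate synthesis/uptake and pyrimidine precursors
ASPS: OAA (abcd) -> ASP (abcd)
ASPUP: ASPX (abcd) -> ASP (abcd)
CPS: CO2 (a) -> CAP (a)
#
# Nucleotide synthesis: de novo versus salvage. UMP drops the aspartate
# alpha-carboxyl at OMP decarboxylation; IMP ring takes glycine C1-C2,
# two one-carbon units and one CO2 on a ribose-5-phosphate moiety.
UMPS: R5P (abcde) + ASP (fghi) + CAP (j) -> UMP (abcdeghij) + CO2 (f)
UMPSAL: URD (abcdefghi) -> UMP (abcdefghi)
IMPS: R5P (abcde) + GLY (fg) + MEETHF (h) + MEETHF (i) + CO2 (j) -> IMP (abcdefghij)
IMPSAL: INS (abcdefghij) -> IMP (abcdefghij)
#
# Branch-point reporter registry (exact under a pure [U-13C]glucose tracer
# with unlabeled exogenous sources; see vignette). The named share is the
# flux fraction of the given reaction among the pool's producers.
BRANCH SER SSP : m("SER",3) / m("3PG",3)
BRANCH GLY SHMT : m("GLY",2) / m("SER",3)
BRANCH ASP ASPS : L("ASP") / L("OAA")
BRANCH OAA PC : m("OAA",3) / (m("OAA",3) + m("OAA",4))
BRANCH IMP IMPS : L("IMP") / (1 - m0("R5P") * m0("GLY") * (1 - m("SER",3))^2)
BRANCH UMP UMPS : L("UMP") / (1 - m0("R5P") * m0("ASP"))
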