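# Default single-compartment TCA-cycle network with atom maps.
# Pool sizes are per-cell amounts in arbitrary units (defaults; scenario
# configs may override them per cell-cycle position bin).
#
# Sources: Pyr.ext (glycolytic pyruvate, tracer-controlled), Gln
# (glutamine, tracer-controlled), CO2 (unlabeled, never balanced).
# Sink metabolites (*.snk) absorb efflux carbon and are never balanced.

met: Pyr.ext, 3, 1.0, source, 0.0
met: Gln,     5, 1.0, source, 0.0
met: CO2,     1, 1.0, source, 0.0
met: Pyr,     3, 1.0, balanced, 0.0
met: AcCoA,   2, 0.2, balanced, 0.0
met: Cit,     6, 2.0, balanced, 0.0
met: AKG,     5, 1.0, balanced, 0.0
met: Suc,     4, 0.5, balanced, 0.0, symmetric
met: Fum,     4, 0.3, balanced, 0.0, symmetric
met: Mal,     4, 1.0, balanced, 0.0
met: OAA,     4, 0.1, balanced, 0.0
met: Glu,     5, 5.0, balanced, 0.0
met: Cit.snk, 6, 1.0, source, 0.0
met: Glu.snk, 5, 1.0, source, 0.0
met: OAA.snk, 4, 1.0, source, 0.0

# glycolysis-fed pyruvate
PYRt:  Pyr.ext (abc) -> Pyr (abc)
# pyruvate dehydrogenase (C1 released as CO2)
PDH:   Pyr (abc) -> AcCoA (bc) + CO2 (a)
# pyruvate carboxylase (CO2 fixed as OAA C4)
PC:    Pyr (abc) + CO2 (d) -> OAA (abcd)
# citrate synthase
CS:    OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)
# oxidative citrate -> alpha-ketoglutarate (IDH/aconitase lumped)
IDH:   Cit (abcdef) -> AKG (abcde) + CO2 (f)
# reductive carboxylation (reverse IDH mapping)
RC:    AKG (abcde) + CO2 (f) -> Cit (abcdef)
# alpha-KG dehydrogenase + succinyl-CoA synthetase (C1 released)
AKGDH: AKG (abcde) -> Suc (bcde) + CO2 (a)
# glutaminase (glutamine entry)
GLS:   Gln (abcde) -> Glu (abcde)
# glutamate dehydrogenase / transaminases
GDH:   Glu (abcde) -> AKG (abcde)
# succinate dehydrogenase
SDH:   Suc (abcd) -> Fum (abcd)
# fumarase
FH:    Fum (abcd) -> Mal (abcd)
# malate dehydrogenase
MDH:   Mal (abcd) -> OAA (abcd)
# ATP-citrate lyase (inverse of the CS mapping)
ACL:   Cit (abcdef) -> AcCoA (ed) + OAA (fcba)
# effluxes to biosynthesis
CITout: Cit (abcdef) -> Cit.snk (abcdef)
GLUout: Glu (abcde) -> Glu.snk (abcde)
OAAout: OAA (abcd) -> OAA.snk (abcd)
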