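# In-repo fixture molecules: 237 small, valid, drug-like SMILES covering the
# supported element list, aromatic rings, charged atoms and E/Z double bonds.
# Every fixture has at least three atoms and at least one absent edge, so all
# of them support 1:1 negative sampling during pre-training. Labels are
# frozen ring-membership flags (1 if the molecule contains a ring), the
# structural rule used by the synthetic classification task.

FIXTURE_SMILES <- c(
    "CC(=O)Oc1ccccc1C(=O)O",
    "CC(=O)Nc1ccc(O)cc1",
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "CN1C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",
    "NC(=O)c1ccc[nH0]c1",
    "OCC1OC(O)C(O)C(O)C1O",
    "NCCc1ccc(O)c(O)c1",
    "CC(N)Cc1ccccc1",
    "NC(Cc1ccccc1)C(=O)O",
    "NC(CO)C(=O)O",
    "NC(CS)C(=O)O",
    "OC(=O)CC(O)(CC(=O)O)C(=O)O",
    "OC(=O)/C=C/C(=O)O",
    "OC(=O)/C=C\\C(=O)O",
    "C/C=C/C=O",
    "CC(=O)OCC[N+](C)(C)C",
    "[O-]C(=O)c1ccccc1",
    "C[N+](C)(C)CC(O)CC([O-])=O",
    "Nc1ccc(cc1)S(N)(=O)=O",
    "Clc1ccccc1",
    "Brc1ccccc1",
    "Fc1ccccc1",
    "Ic1ccccc1",
    "c1ccc2ccccc2c1",
    "c1ccc2[nH]ccc2c1",
    "c1ccncc1",
    "c1ccoc1",
    "c1ccsc1",
    "c1cc[nH]c1",
    "c1cnc2[nH]cnc2n1",
    "O=c1cc[nH]c(=O)[nH]1",
    "Cc1cc[nH]c(=O)n1",
    "Nc1ncnc2[nH]cnc12",
    "CSCCC(N)C(=O)O",
    "OCC(O)C(O)C(O)C(O)CO",
    "CCOC(=O)c1ccccc1",
    "COc1ccc(CCN)cc1",
    "CN(C)CCc1c[nH]c2ccccc12",
    "OC(c1ccccc1)c1ccccc1",
    "O=C(Nc1ccccc1)c1ccccc1",
    "CC(C)NCC(O)COc1ccccc1",
    "CN1CCC[C@H]1c1cccnc1",
    "CC(C)(C)NCC(O)c1ccc(O)c(O)c1",
    "OCCN1CCN(CCCN2c3ccccc3Sc3ccccc32)CC1",
    "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    "Oc1ccc(cc1)C(O)CNC",
    "NS(=O)(=O)c1cc2c(cc1Cl)NC(NS2(=O)=O)C",
    "OC(=O)c1cc(O)c(O)c(O)c1",
    "COc1cc(C=O)ccc1O",
    "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
    "CC(C)=CCO",
    "CC(C)=CC(=O)C",
    "C1CCNCC1",
    "C1CCOC1",
    "C1CCOCC1",
    "C1CCSCC1",
    "C1CCC2CCCCC2C1",
    "C1CCC1",
    "C1CCCC1",
    "C1CCCCC1",
    "C1CCCCCC1",
    "CC#N",
    "CC#CC",
    "N#Cc1ccccc1",
    "CC(C)O",
    "CC(C)=O",
    "CCOCC",
    "CCSCC",
    "CCNCC",
    "O=S(=O)(O)O.CCN",
    "CCCCCCCCC",
    "CC(C)CC(C)(C)C",
    "OCCO",
    "OCC(O)CO",
    "C(Cl)(Cl)Cl",
    "ClCCl",
    "FC(F)(F)c1ccccc1",
    "CC(=O)C",
    "CC=O",
    "OC=O",
    "CCO",
    "C[Si](C)(C)C",
    "B(O)(O)c1ccccc1",
    "O=P(O)(O)OCC",
    "CCS",
    "CS(=O)C",
    "O=[Se]=O",
    "[Se]1C=CC=C1",
    "[Fe+2].[O-]C(=O)C",
    "OC[C@H](N)C(=O)O",
    "C[Sn](C)(C)C",
    "[As](=O)(O)(O)O",
    "CC[Zn]CC",
    "O=C1CCCCC1",
    "O=C1CCCC1",
    "OC1CCCCC1",
    "N1CCNCC1",
    "O1CCOCC1",
    "Cc1ccccc1C",
    "Cc1ccccc1",
    "CCc1ccccc1",
    "COc1ccccc1",
    "Oc1ccccc1",
    "Nc1ccccc1",
    "CC(=O)c1ccccc1",
    "O=Cc1ccccc1",
    "OC(=O)c1ccccc1",
    "C/C=C/C",
    "C/C=C\\C",
    "CC=CC",
    "CN(C)C=O",
    "CC(=O)N(C)C",
    "O=C(N)N",
    "NC(=N)N",
    "CSC",
    "CC(C)S",
    "OS(=O)(=O)c1ccccc1",
    "ClC(Cl)=C(Cl)Cl",
    "FC=CF",
    "F/C=C/F",
    "F/C=C\\F",
    "N[C@@H](C)C(=O)O",
    "CC(C)C[C@H](N)C(=O)O",
    "Cc1ncc(CO)c(C=O)c1O",
    "OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O",
    "CC(C)(C)OC(=O)N",
    "CCOC(=O)C",
    "CCCCN",
    "CCCCO",
    "CCCC(=O)O",
    "CCCC=O",
    "C1=CC2=CC=CC3=C2C(=C1)C=C3",
    "c1ccc(cc1)c1ccccc1",
    "c1ccc(Cc2ccccc2)cc1",
    "O=C(c1ccccc1)c1ccccc1",
    "c1ccc(Oc2ccccc2)cc1",
    "C(=O)(O)CN",
    "NCCO",
    "NCCN",
    "OCCN",
    "CC(O)C(=O)O",
    "OC(=O)C(=O)O",
    "OC(=O)CC(=O)O",
    "CC(=CC(=O)O)C",
    "CC(=O)CC(=O)C",
    "Cn1ccnc1",
    "Cn1cccc1",
    "Cc1occc1",
    "Cc1sccc1",
    "O=c1ccocc1",
    "C1CN2CCC1CC2",
    "C1CC2CCC1CC2",
    "C1CC2CC1CC2",
    "OC1CC2CCC1(C)C2(C)C",
    "CC1=CCC(CC1)C(C)C",
    "CC(C)C1CCC(C)CC1O",
    "CC1=CC(=O)CC(C)(C)C1",
    "c1ccc2c(c1)ncs2",
    "c1ccc2c(c1)oc(=O)cc2",
    "c1ccc2c(c1)[nH]c(=O)[nH]c2=O",
    "Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl",
    "CCN(CC)C(=O)C",
    "CCN(CC)CC",
    "CN(C)CCCN",
    "NCCCN",
    "NCCCCN",
    "OB(O)O",
    "OP(=O)(O)O",
    "OS(=O)(=O)O",
    "O=S(=O)(N)c1ccccc1",
    "S=C=S",
    "O=C=O",
    "CC(C)(C)c1ccccc1",
    "CC(C)(C)O",
    "CC(Cl)CC",
    "CC(Br)CC",
    "CCI",
    "C(F)(F)F",
    "CC(F)(F)F",
    "Oc1ccc(Cl)cc1",
    "Oc1ccc(Br)cc1",
    "Nc1ccc(F)cc1",
    "COC(=O)c1ccc(N)cc1",
    "CCOC(=O)c1ccc(N)cc1",
    "CN1CCCC1=O",
    "O=C1CCCCN1",
    "O=C1CCCN1",
    "O=C1OCCC1",
    "CC1(C)OC(=O)CC1",
    "CC(=O)SC",
    "CC(=S)N",
    "[NH4+].[O-]C(=O)C",
    "CCCCCC=O",
    "CCCCC(=O)C",
    "CCCCCO",
    "CCCCCN",
    "CC(N)C(=O)NC(C)C(=O)O",
    "NC(CC(=O)O)C(=O)O",
    "NC(CCC(=O)O)C(=O)O",
    "NC(Cc1ccc(O)cc1)C(=O)O",
    "NC(Cc1c[nH]cn1)C(=O)O",
    "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    "NC(CCCNC(=N)N)C(=O)O",
    "NC(CCCCN)C(=O)O",
    "OC1CCCC1",
    "OC1CCC1",
    "NC1CCCCC1",
    "O=C(O)C1CCCCC1",
    "O=CC1CCCCC1",
    "CC1CCCCC1",
    "CCC1CCCCC1",
    "c1cnc2ccccc2c1",
    "c1cnc2ncccc2c1",
    "c1ccc2cc3ccccc3cc2c1",
    "Clc1cccc(Cl)c1",
    "Clc1ccc(Cl)cc1",
    "Oc1cccc(O)c1",
    "Oc1ccc(O)cc1",
    "Oc1ccccc1O",
    "Nc1cccc(N)c1",
    "COc1ccc(OC)cc1",
    "O=[N+]([O-])c1ccccc1",
    "O=[N+]([O-])c1ccc(N)cc1",
    "Cc1ccc(cc1)S(=O)(=O)O",
    "Cc1ccc(cc1)S(=O)(=O)N",
    "CC(=O)Nc1ccc(cc1)S(N)(=O)=O",
    "CCN(CC)c1ccccc1",
    "CN(C)c1ccccc1",
    "O=C(OC)C=C",
    "C=CC(=O)O",
    "C=CC#N",
    "C=Cc1ccccc1",
    "CC(=C)C(=O)OC",
    "C=C(C)C",
    "CCCCCCCCCCCCCCCC(=O)O",
    "CCCCCCCC/C=C\\CCCCCCCC(=O)O")

FIXTURE_LABELS <- c(
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0,
  0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0,
  0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0,
  0, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0,
  0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0, 0, 1, 0, 0, 0, 0)

#' Fixture molecules
#'
#' A deterministic list of 237 small drug-like molecules embedded in the
#' package, each with a structural label (1 if the molecule contains a ring).
#' Every fixture parses with [smiles_to_graph()], has at least one bond and
#' at least one absent edge.
#'
#' @return data.frame with columns `smiles` and `label`.
#' @export
fixture_molecules <- function() {
  data.frame(smiles = FIXTURE_SMILES, label = FIXTURE_LABELS,
             stringsAsFactors = FALSE)
}
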