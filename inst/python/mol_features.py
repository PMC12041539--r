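"""Extract per-atom and per-bond descriptors from SMILES with RDKit.

Usage: python mol_features.py <smiles.txt> <out.json>

Input: one SMILES per line. Output: JSON array, one entry per line;
an unparsable SMILES yields null. Heavy-atom graph (implicit hydrogens).
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()

HYB = {
    Chem.HybridizationType.SP: "sp",
    Chem.HybridizationType.SP2: "sp2",
    Chem.HybridizationType.SP3: "sp3",
    Chem.HybridizationType.SP3D: "sp3d",
    Chem.HybridizationType.SP3D2: "sp3d2",
}

BOND = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}

STEREO = {
    Chem.BondStereo.STEREONONE: "none",
    Chem.BondStereo.STEREOANY: "any",
    Chem.BondStereo.STEREOE: "E",
    Chem.BondStereo.STEREOTRANS: "E",
    Chem.BondStereo.STEREOZ: "Z",
    Chem.BondStereo.STEREOCIS: "Z",
}


def describe(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None or mol.GetNumAtoms() == 0:
        return None
    atoms = []
    for a in mol.GetAtoms():
        z = a.GetAtomicNum()
        atoms.append(
            {
                "element": a.GetSymbol(),
                "formal_charge": a.GetFormalCharge(),
                "degree": a.GetDegree(),
                "hybridization": HYB.get(a.GetHybridization(), "other"),
                "in_ring": int(a.IsInRing()),
                "aromatic": int(a.GetIsAromatic()),
                "mass": a.GetMass(),
                "vdw_radius": PT.GetRvdw(z),
                "covalent_radius": PT.GetRcovalent(z),
            }
        )
    bonds = []
    for b in mol.GetBonds():
        bonds.append(
            {
                "i": b.GetBeginAtomIdx() + 1,  # 1-based for R
                "j": b.GetEndAtomIdx() + 1,
                "order": BOND.get(b.GetBondType(), "other"),
                "conjugated": int(b.GetIsConjugated()),
                "stereo": STEREO.get(b.GetStereo(), "none"),
            }
        )
    return {"atoms": atoms, "bonds": bonds}


def main(argv):
    src, dst = argv[1], argv[2]
    with open(src) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    out = [describe(s) for s in smiles]
    with open(dst, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv)
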