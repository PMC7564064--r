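"""JSON bridge between the ecoqsar R package and RDKit.

Reads one JSON document on stdin:

  {"molecules": [{"id": "...", "smiles": "..."} | {"id": "...", "molblock": "..."}],
   "settings": {"seed": 42, "max_iterations": 10000, "convergence": 0.005,
                "add_hs": true},
   "tasks": ["parse", "embed", "params"],
   "match_smarts": "optional SMARTS pattern"}

and writes one JSON document with per-molecule results on stdout. Per-molecule
failures are reported in-band ({"ok": false, "error": ...}) so a bad product
in a batch never aborts the batch. Atom order is RDKit's canonical input
order and is deterministic for identical input text; 3D embedding uses
seeded ETKDGv3 followed by MMFF94 (UFF fallback) minimization, so identical
seed implies identical coordinates.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()


def parse_one(entry, add_hs):
    if entry.get("smiles") is not None:
        mol = Chem.MolFromSmiles(entry["smiles"])
        if mol is None:
            raise ValueError("unparsable SMILES: %r" % entry["smiles"])
    elif entry.get("molblock") is not None:
        mol = Chem.MolFromMolBlock(entry["molblock"], removeHs=False)
        if mol is None:
            raise ValueError("unparsable MOL/SDF block for id %r" % entry.get("id"))
    else:
        raise ValueError("molecule entry needs 'smiles' or 'molblock'")
    if add_hs:
        mol = Chem.AddHs(mol)
    return mol


def embed_one(mol, settings):
    params = AllChem.ETKDGv3()
    params.randomSeed = int(settings.get("seed", 42))
    conf_id = AllChem.EmbedMolecule(mol, params)
    if conf_id < 0:
        raise ValueError("3D embedding failed")
    props = AllChem.MMFFGetMoleculeProperties(mol)
    if props is not None:
        ff = AllChem.MMFFGetMoleculeForceField(mol, props, confId=conf_id)
    else:
        ff = AllChem.UFFGetMoleculeForceField(mol, confId=conf_id)
    if ff is None:
        raise ValueError("no force field available for molecule")
    e0 = ff.CalcEnergy()
    ff.Minimize(maxIts=int(settings.get("max_iterations", 10000)),
                energyTol=float(settings.get("convergence", 0.005)))
    e1 = ff.CalcEnergy()
    return e0, e1


def params_one(mol):
    AllChem.ComputeGasteigerCharges(mol)
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    charges, steric, hydrophobic, donor, acceptor = [], [], [], [], []
    for atom in mol.GetAtoms():
        q = float(atom.GetProp("_GasteigerCharge"))
        if not math.isfinite(q):
            raise ValueError("non-finite Gasteiger charge on atom %d (%s)"
                             % (atom.GetIdx(), atom.GetSymbol()))
        rvdw = PT.GetRvdw(atom.GetAtomicNum())
        if rvdw <= 0:
            raise ValueError("no van der Waals radius for element %s"
                             % atom.GetSymbol())
        charges.append(q)
        steric.append(rvdw ** 3)
        hydrophobic.append(float(crippen[atom.GetIdx()][0]))
        sym = atom.GetSymbol()
        donor.append(sym in ("N", "O", "S") and atom.GetTotalNumHs(includeNeighbors=True) > 0)
        acceptor.append(sym in ("N", "O") and atom.GetFormalCharge() <= 0)
    return charges, steric, hydrophobic, donor, acceptor


def process(entry, settings, tasks, pattern):
    mol = parse_one(entry, settings.get("add_hs", True))
    out = {
        "id": entry.get("id"),
        "ok": True,
        "symbol": [a.GetSymbol() for a in mol.GetAtoms()],
        "mass": [PT.GetAtomicWeight(a.GetAtomicNum()) for a in mol.GetAtoms()],
        "aromatic": [a.GetIsAromatic() for a in mol.GetAtoms()],
        "formal_charge": Chem.GetFormalCharge(mol),
        "n_heavy": mol.GetNumHeavyAtoms(),
        "canonical_smiles": Chem.MolToSmiles(Chem.RemoveHs(mol)),
    }
    if "embed" in tasks:
        e0, e1 = embed_one(mol, settings)
        conf = mol.GetConformer()
        out["coords"] = [[p.x, p.y, p.z] for p in
                         (conf.GetAtomPosition(i) for i in range(mol.GetNumAtoms()))]
        out["energy_initial"] = e0
        out["energy_final"] = e1
        out["molblock"] = Chem.MolToMolBlock(mol)
    if "params" in tasks:
        charges, steric, hydrophobic, donor, acceptor = params_one(mol)
        out["charge"] = charges
        out["steric"] = steric
        out["hydrophobic"] = hydrophobic
        out["donor"] = donor
        out["acceptor"] = acceptor
    if pattern is not None:
        patt = Chem.MolFromSmarts(pattern)
        if patt is None:
            raise ValueError("invalid SMARTS pattern: %r" % pattern)
        match = mol.GetSubstructMatch(patt)
        out["match"] = list(match)
        out["n_matches"] = len(mol.GetSubstructMatches(patt))
    return out


def main():
    request = json.load(sys.stdin)
    settings = request.get("settings") or {}
    tasks = request.get("tasks") or ["parse"]
    pattern = request.get("match_smarts")
    results = []
    for entry in request.get("molecules", []):
        try:
            results.append(process(entry, settings, tasks, pattern))
        except Exception as exc:  # per-molecule error, batch continues
            results.append({"id": entry.get("id"), "ok": False, "error": str(exc)})
    json.dump({"molecules": results}, sys.stdout)


if __name__ == "__main__":
    main()
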