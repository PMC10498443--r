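"""JSON bridge to RDKit used by the confsmith R package.

Two services are provided, both reading a JSON request from stdin and
writing a JSON response to stdout:

  parse  -- read SMILES strings or MOL/SDF blocks into annotated
            connection tables (elements, charges, bond orders, aromatic
            flags, implicit hydrogen counts, stereo descriptors and
            optional 3D coordinates).
  params -- type a hydrogen-complete molecule (supplied as a V2000 mol
            block) with the validated RDKit MMFF94/MMFF94s implementation
            and return the decomposed interaction lists (bond stretching,
            angle bending, stretch-bend, out-of-plane, torsion, van der
            Waals, partial charges), plus SMARTS substructure matches for
            torsion-rule assignment.

All atom indices in the JSON exchange are 0-based; the R side converts.
Stereo conventions (established empirically against RDKit and relied on
by the R side):
  * AddHs appends hydrogens after the heavy atoms, grouped by parent
    atom in ascending parent order.
  * For a tetrahedral centre the reported parity is the sign of the
    signed volume (n2-n1).((n3-n1)x(n4-n1)) over the four neighbours in
    ascending index order: CHI_TETRAHEDRAL_CW -> +1, CCW -> -1,
    multiplied by the parity of the permutation taking the bond-list
    neighbour order to ascending order.
  * Double-bond "cis" means the two stereo reference atoms lie on the
    same side of the bond axis.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import ChemicalForceFields  # noqa: F401 (registers MMFF bindings)
from rdkit.Chem import rdForceFieldHelpers as FF
from rdkit.Chem import rdmolops

RDLogger.DisableLog("rdApp.*")

PT = Chem.GetPeriodicTable()


def perm_parity(p):
    p = list(p)
    par = 1
    for i in range(len(p)):
        while p[i] != i:
            j = p[i]
            p[i], p[j] = p[j], p[i]
            par = -par
    return par


def atom_parity(atom):
    """Signed-volume parity over ascending-index neighbours, or 0."""
    tag = atom.GetChiralTag()
    if tag == Chem.ChiralType.CHI_TETRAHEDRAL_CW:
        s = 1
    elif tag == Chem.ChiralType.CHI_TETRAHEDRAL_CCW:
        s = -1
    else:
        return 0
    nbrs = [b.GetOtherAtomIdx(atom.GetIdx()) for b in atom.GetBonds()]
    if len(nbrs) != 4:
        return 0
    srt = sorted(nbrs)
    perm = [srt.index(x) for x in nbrs]
    return s * perm_parity(perm)


def parse_record(rec):
    if "smiles" in rec:
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            return {"ok": False, "error": "unparsable SMILES"}
    else:
        mol = Chem.MolFromMolBlock(rec["molblock"], removeHs=False)
        if mol is None:
            return {"ok": False, "error": "unparsable MOL block"}
    name = rec.get("name") or (mol.GetProp("_Name") if mol.HasProp("_Name") else "")

    has3d = mol.GetNumConformers() > 0 and mol.GetConformer().Is3D()
    if has3d:
        Chem.AssignStereochemistryFrom3D(mol)
    else:
        Chem.AssignStereochemistry(mol, cleanIt=True, force=True)

    nheavy_in = mol.GetNumAtoms()
    # Parities must refer to the hydrogen-complete index space the R side
    # will construct (H appended grouped by parent in parent order).
    molH = Chem.AddHs(mol)
    atoms = []
    for a in mol.GetAtoms():
        cip = a.GetPropsAsDict().get("_CIPCode", None)
        atoms.append({
            "el": a.GetSymbol(),
            "chg": a.GetFormalCharge(),
            "nH": a.GetTotalNumHs(),  # implicit + bracket H count, excl. H atoms
            "arom": bool(a.GetIsAromatic()),
            "cip": cip,
        })
    bonds = []
    kek = Chem.Mol(mol)
    Chem.Kekulize(kek, clearAromaticFlags=False)
    for b in kek.GetBonds():
        order = int(b.GetBondTypeAsDouble())
        bonds.append({
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "order": max(order, 1),
            "arom": bool(mol.GetBondWithIdx(b.GetIdx()).GetIsAromatic()),
        })
    stereo_atoms = []
    for a in molH.GetAtoms():
        par = atom_parity(a)
        if par != 0:
            cip = None
            if a.GetIdx() < nheavy_in:
                cip = mol.GetAtomWithIdx(a.GetIdx()).GetPropsAsDict().get("_CIPCode", None)
            stereo_atoms.append({
                "center": a.GetIdx(),
                "nbrs": sorted(b.GetOtherAtomIdx(a.GetIdx()) for b in a.GetBonds()),
                "parity": par,
                "cip": cip,
            })
    stereo_bonds = []
    for b in mol.GetBonds():
        st = b.GetStereo()
        if st == Chem.BondStereo.STEREONONE:
            continue
        sa = list(b.GetStereoAtoms())
        if len(sa) != 2:
            continue
        if st in (Chem.BondStereo.STEREOZ, Chem.BondStereo.STEREOCIS):
            cfg = "cis"
        elif st in (Chem.BondStereo.STEREOE, Chem.BondStereo.STEREOTRANS):
            cfg = "trans"
        else:
            continue
        stereo_bonds.append({
            "a": b.GetBeginAtomIdx(),
            "b": b.GetEndAtomIdx(),
            "ref_a": sa[0],
            "ref_b": sa[1],
            "config": cfg,
        })
    coords = None
    if has3d:
        conf = mol.GetConformer()
        coords = [[conf.GetAtomPosition(i).x,
                   conf.GetAtomPosition(i).y,
                   conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
    return {
        "ok": True,
        "name": name,
        "atoms": atoms,
        "bonds": bonds,
        "coords": coords,
        "stereo_atoms": stereo_atoms,
        "stereo_bonds": stereo_bonds,
    }


LINEAR_MMFF_TYPES = {4, 42, 53, 60, 61}


def params_record(molblock, variant, smarts_list):
    mol = Chem.MolFromMolBlock(molblock, removeHs=False)
    if mol is None:
        return {"ok": False, "error": "unparsable MOL block"}
    if not FF.MMFFHasAllMoleculeParams(mol):
        return {"ok": False, "error": "atom(s) outside MMFF94 parameter coverage"}
    props = FF.MMFFGetMoleculeProperties(mol, mmffVariant=variant)
    if props is None:
        return {"ok": False, "error": "MMFF94 atom typing failed"}
    n = mol.GetNumAtoms()
    at = [props.GetMMFFAtomType(i) for i in range(n)]
    charges = [props.GetMMFFPartialCharge(i) for i in range(n)]
    out = {"ok": True, "atom_types": at, "charges": charges,
           "bonds": [], "angles": [], "sb": [], "oop": [], "tors": [], "nb": []}
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        p = props.GetMMFFBondStretchParams(mol, i, j)
        if p is None:
            return {"ok": False,
                    "error": "missing bond parameters for atoms %d-%d" % (i, j)}
        out["bonds"].append([i, j, p[1], p[2]])
    import itertools
    for j in range(n):
        nbrs = [a.GetIdx() for a in mol.GetAtomWithIdx(j).GetNeighbors()]
        for i, k in itertools.combinations(nbrs, 2):
            p = props.GetMMFFAngleBendParams(mol, i, j, k)
            if p is not None:
                out["angles"].append([i, j, k, p[1], p[2],
                                      1 if at[j] in LINEAR_MMFF_TYPES else 0])
            ps = props.GetMMFFStretchBendParams(mol, i, j, k)
            if ps is not None:
                pb1 = props.GetMMFFBondStretchParams(mol, i, j)
                pb2 = props.GetMMFFBondStretchParams(mol, k, j)
                pa = props.GetMMFFAngleBendParams(mol, i, j, k)
                if pb1 is not None and pb2 is not None and pa is not None:
                    out["sb"].append([i, j, k, ps[1], ps[2],
                                      pb1[2], pb2[2], pa[2]])
        if len(nbrs) == 3:
            for l in range(3):
                i, k = [nbrs[x] for x in range(3) if x != l]
                p = props.GetMMFFOopBendParams(mol, i, j, k, nbrs[l])
                if p:
                    out["oop"].append([i, j, k, nbrs[l], p])
    for b in mol.GetBonds():
        j, k = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        for ai in mol.GetAtomWithIdx(j).GetNeighbors():
            i = ai.GetIdx()
            if i == k:
                continue
            for al in mol.GetAtomWithIdx(k).GetNeighbors():
                l = al.GetIdx()
                if l == j or l == i:
                    continue
                p = props.GetMMFFTorsionParams(mol, i, j, k, l)
                if p is not None:
                    out["tors"].append([i, j, k, l, p[1], p[2], p[3]])
    td = rdmolops.GetDistanceMatrix(mol)
    for i in range(n):
        for j in range(i + 1, n):
            if td[i][j] < 3:
                continue
            v = props.GetMMFFVdWParams(i, j)
            scale = 0.75 if td[i][j] == 3 else 1.0
            # fields 2,3 carry the donor/acceptor-scaled R*_ij and epsilon
            out["nb"].append([i, j, v[2], v[3],
                              charges[i] * charges[j] * scale, int(td[i][j])])
    matches = []
    for sm in smarts_list:
        patt = Chem.MolFromSmarts(sm)
        if patt is None:
            matches.append(None)
            continue
        ms = mol.GetSubstructMatches(patt, uniquify=False, maxMatches=5000)
        matches.append([list(m) for m in ms])
    out["matches"] = matches
    return out


def main():
    req = json.load(sys.stdin)
    cmd = req["cmd"]
    if cmd == "parse":
        res = [parse_record(r) for r in req["records"]]
    elif cmd == "params":
        variant = req.get("variant", "MMFF94s")
        smarts = req.get("smarts", [])
        res = [params_record(mb, variant, smarts) for mb in req["molblocks"]]
    else:
        res = {"error": "unknown command"}
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
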