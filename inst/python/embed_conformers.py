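"""Batch 3D conformer generation: ETKDG embedding + MMFF94 minimisation.

Usage: python embed_conformers.py <in.smi> <out.txt> <seed>

Input: one molecule per line, "SMILES TAG". Output blocks:

    #BEGIN <tag>
    #STATUS ok|parse_fail|embed_fail <minimized: 1|0|-1>
    <element> <x> <y> <z>        (one line per atom, explicit hydrogens)
    #END

minimized: 1 converged, 0 ran but not converged, -1 force-field setup
failed (coordinates are then the raw embedding).
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return "parse_fail", None, 0
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) < 0:
        return "embed_fail", None, 0
    try:
        ret = AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
        minimized = 1 if ret == 0 else (0 if ret == 1 else -1)
    except Exception:
        minimized = -1
    return "ok", mol, minimized


def main(inp, out, seed):
    with open(inp) as fh:
        lines = [ln.strip() for ln in fh if ln.strip()]
    with open(out, "w") as fh:
        for ln in lines:
            parts = ln.split()
            smi = parts[0]
            tag = parts[1] if len(parts) > 1 else parts[0]
            status, mol, minimized = embed(smi, seed)
            fh.write("#BEGIN %s\n#STATUS %s %d\n" % (tag, status, minimized))
            if status == "ok":
                conf = mol.GetConformer()
                for atom in mol.GetAtoms():
                    p = conf.GetAtomPosition(atom.GetIdx())
                    fh.write("%s %.8f %.8f %.8f\n"
                             % (atom.GetSymbol(), p.x, p.y, p.z))
            fh.write("#END\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]))
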