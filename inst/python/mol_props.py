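"""Batch molecular property helper.

Reads SMILES (one per line) from argv[1]; writes a TSV to argv[2] with
columns: line index, valid flag, canonical SMILES, QED, SAS, heavy-atom
count. Invalid lines get flag 0 and empty/NA fields. QED is RDKit's
reference implementation of the eight-property geometric-mean
drug-likeness estimate; SAS is the fragment-based synthetic
accessibility score from the RDKit contrib tree.
"""
import os
import sys

from rdkit import Chem, RDConfig, RDLogger

RDLogger.DisableLog("rdApp.*")
from rdkit.Chem import QED  # noqa: E402

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def main(inp, out):
    with open(inp) as fin, open(out, "w") as fout:
        for i, line in enumerate(fin):
            smi = line.rstrip("\n")
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                fout.write(f"{i}\t0\t\tNA\tNA\tNA\n")
                continue
            try:
                q = QED.qed(mol)
            except Exception:
                q = float("nan")
            try:
                s = sascorer.calculateScore(mol)
            except Exception:
                s = float("nan")
            can = Chem.MolToSmiles(mol)
            fout.write(f"{i}\t1\t{can}\t{q!r}\t{s!r}\t{mol.GetNumHeavyAtoms()}\n")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
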