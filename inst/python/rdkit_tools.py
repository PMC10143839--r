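"""Batched RDKit helper for the dfikit R package.

Reads a CSV with columns (id, smiles), writes a CSV back. Invoked once per
table, never per molecule. Subcommands:

  canonical  -> id, canonical_smiles ('' on parse failure), error
  fp         -> id, onbits (space-separated on-bit indices of a Morgan
                fingerprint; '' allowed for a molecule with no bits set),
                error
  desc       -> id + the 60 MOE-type descriptor columns

The 60-descriptor registry follows the PyBioMed/MOE convention:
slogPVSA0..11, MRVSA0..9, PEOEVSA0..13, EstateVSA0..10, VSAEstate0..10,
LabuteASA, MTPSA.  VSA_EState is binned over the E-state bin edges
(10 edges -> 11 values), the legacy convention under which index 10 exists.
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdMolDescriptors


def _quiet():
    RDLogger.DisableLog("rdApp.*")


def _read_rows(path):
    with open(path, newline="") as fh:
        return list(csv.DictReader(fh))


def _write_rows(path, fieldnames, rows):
    with open(path, "w", newline="") as fh:
        w = csv.DictWriter(fh, fieldnames=fieldnames)
        w.writeheader()
        w.writerows(rows)


def _mol(smiles):
    if smiles is None or smiles == "":
        return None, "empty SMILES"
    m = Chem.MolFromSmiles(smiles)
    if m is None:
        return None, "unparseable SMILES: %s" % smiles
    return m, ""


def cmd_canonical(args):
    out = []
    for row in _read_rows(args.infile):
        m, err = _mol(row["smiles"])
        can = Chem.MolToSmiles(m) if m is not None else ""
        out.append({"id": row["id"], "canonical_smiles": can, "error": err})
    _write_rows(args.outfile, ["id", "canonical_smiles", "error"], out)


def cmd_fp(args):
    gen = rdMolDescriptors.GetMorganFingerprintAsBitVect
    out = []
    for row in _read_rows(args.infile):
        m, err = _mol(row["smiles"])
        bits = ""
        if m is not None:
            fp = gen(m, args.radius, nBits=args.nbits)
            bits = " ".join(str(i) for i in fp.GetOnBits())
        out.append({"id": row["id"], "onbits": bits, "error": err})
    _write_rows(args.outfile, ["id", "onbits", "error"], out)


# ---- 60-descriptor registry ------------------------------------------------

def registry_names():
    names = ["slogPVSA%d" % i for i in range(12)]
    names += ["MRVSA%d" % i for i in range(10)]
    names += ["PEOEVSA%d" % i for i in range(14)]
    names += ["EstateVSA%d" % i for i in range(11)]
    names += ["VSAEstate%d" % i for i in range(11)]
    names += ["LabuteASA", "MTPSA"]
    return names


def descriptor_values(m):
    from rdkit.Chem.EState import EState_VSA

    vals = list(rdMolDescriptors.SlogP_VSA_(m))          # 12
    vals += list(rdMolDescriptors.SMR_VSA_(m))           # 10
    vals += list(rdMolDescriptors.PEOE_VSA_(m))          # 14
    vals += list(EState_VSA.EState_VSA_(m))              # 11
    # legacy 11-slot VSA_EState binning (estateBins edges)
    vals += list(EState_VSA.VSA_EState_(m, bins=EState_VSA.estateBins))  # 11
    vals.append(Descriptors.LabuteASA(m))
    vals.append(Descriptors.TPSA(m))
    return vals


def cmd_desc(args):
    names = registry_names()
    out = []
    for row in _read_rows(args.infile):
        m, err = _mol(row["smiles"])
        rec = {"id": row["id"], "error": err}
        if m is not None:
            for k, v in zip(names, descriptor_values(m)):
                rec[k] = repr(float(v))
        else:
            for k in names:
                rec[k] = ""
        out.append(rec)
    _write_rows(args.outfile, ["id"] + names + ["error"], out)


def main(argv=None):
    _quiet()
    p = argparse.ArgumentParser(prog="rdkit_tools")
    sub = p.add_subparsers(dest="cmd", required=True)
    for name in ("canonical", "fp", "desc"):
        sp = sub.add_parser(name)
        sp.add_argument("--in", dest="infile", required=True)
        sp.add_argument("--out", dest="outfile", required=True)
        if name == "fp":
            sp.add_argument("--radius", type=int, default=2)
            sp.add_argument("--nbits", type=int, default=2048)
    args = p.parse_args(argv)
    {"canonical": cmd_canonical, "fp": cmd_fp, "desc": cmd_desc}[args.cmd](args)
    return 0


if __name__ == "__main__":
    sys.exit(main())
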