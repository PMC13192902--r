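"""Bridge between the plain-text bundle format and AnnData .h5ad files.

Usage:
    python amx_h5ad.py to-h5ad   BUNDLE_DIR OUT.h5ad
    python amx_h5ad.py from-h5ad IN.h5ad    BUNDLE_DIR

The bundle keeps features on rows and samples on columns; AnnData keeps
observations (samples) on rows, so matrices are transposed in both
directions. The first assay maps to X, the rest to layers.
"""
import json
import os
import sys

import numpy as np
import pandas as pd


def read_assay_csv(path, n, p):
    if os.path.getsize(path) == 0 or n == 0 or p == 0:
        return np.zeros((n, p))
    return np.loadtxt(path, delimiter=",", ndmin=2)


def write_assay_csv(mat, path):
    with open(path, "w") as fh:
        for row in np.atleast_2d(mat):
            fh.write(",".join(repr(float(v)) for v in row) + "\n")
        # empty matrices produce an empty file


def read_meta(path, types, has_names):
    df = pd.read_csv(path, sep="\t", dtype=str, keep_default_na=False)
    names = None
    if has_names:
        names = df.iloc[:, 0].tolist()
        df = df.iloc[:, 1:]
    out = {}
    for col in df.columns:
        s = df[col]
        ty = types.get(col, "character")
        if ty in ("double", "integer"):
            out[col] = pd.to_numeric(s.replace("NA", np.nan))
        elif ty == "logical":
            out[col] = s.replace({"TRUE": True, "FALSE": False, "NA": np.nan})
        else:
            out[col] = s.replace("NA", np.nan)
    return pd.DataFrame(out), names


def to_h5ad(bundle, out):
    import anndata as ad

    with open(os.path.join(bundle, "manifest.json")) as fh:
        man = json.load(fh)
    n, p = int(man["shape"][0]), int(man["shape"][1])
    assays = {}
    for a in man["assays"]:
        assays[a["name"]] = read_assay_csv(os.path.join(bundle, a["file"]), n, p)
    var, var_names = read_meta(os.path.join(bundle, man["row_data_file"]),
                               man.get("row_data_types") or {},
                               man.get("row_names_present", False))
    obs, obs_names = read_meta(os.path.join(bundle, man["col_data_file"]),
                               man.get("col_data_types") or {},
                               man.get("col_names_present", False))
    names = list(assays)
    X = assays[names[0]].T if names else np.zeros((p, n))
    layers = {nm: assays[nm].T for nm in names[1:]}
    adata = ad.AnnData(X=X, layers=layers)
    if len(var.columns):
        adata.var = var
    if len(obs.columns):
        adata.obs = obs
    if var_names is not None:
        adata.var_names = var_names
    if obs_names is not None:
        adata.obs_names = obs_names
    adata.uns["amx_first_assay"] = names[0] if names else ""
    adata.uns["amx_assay_dtypes"] = json.dumps(
        {a["name"]: a["dtype"] for a in man["assays"]})
    adata.write_h5ad(out)


def np_meta_type(s):
    if pd.api.types.is_bool_dtype(s):
        return "logical"
    if pd.api.types.is_integer_dtype(s):
        return "integer"
    if pd.api.types.is_float_dtype(s):
        return "double"
    return "character"


def write_meta(df, names, name_col, path):
    out = pd.DataFrame(index=range(df.shape[0]))
    if names is not None:
        out[name_col] = list(names)
    types = {}
    for col in df.columns:
        s = df[col]
        if isinstance(s.dtype, pd.CategoricalDtype):
            s = s.astype(str).where(~df[col].isna())
        types[col] = np_meta_type(s)
        if types[col] == "double":
            vals = ["NA" if pd.isna(v) else repr(float(v)) for v in s]
        elif types[col] == "logical":
            vals = ["NA" if pd.isna(v) else ("TRUE" if v else "FALSE") for v in s]
        else:
            vals = ["NA" if pd.isna(v) else str(v) for v in s]
        out[col] = vals
    out.to_csv(path, sep="\t", index=False)
    return types


def from_h5ad(path, bundle):
    import anndata as ad

    adata = ad.read_h5ad(path)
    os.makedirs(bundle, exist_ok=True)
    p, n = adata.shape
    first = adata.uns.get("amx_first_assay", "X") or "X"
    dtypes = json.loads(adata.uns.get("amx_assay_dtypes", "{}"))
    assays = [(first, np.asarray(adata.X if adata.X is not None
                                 else np.zeros((p, n))))]
    for nm in adata.layers.keys():
        assays.append((nm, np.asarray(adata.layers[nm])))
    manifest_assays = []
    for nm, mat in assays:
        if hasattr(mat, "toarray"):
            mat = mat.toarray()
        fname = "assay_%s.csv" % "".join(c if c.isalnum() or c in "._-" else "_"
                                         for c in nm)
        write_assay_csv(mat.T, os.path.join(bundle, fname))
        manifest_assays.append({"name": nm, "file": fname, "format": "csv",
                                "dtype": dtypes.get(nm, "double")})
    var_names = list(adata.var_names)
    obs_names = list(adata.obs_names)
    rtypes = write_meta(adata.var, var_names, "row_name",
                        os.path.join(bundle, "row_data.tsv"))
    ctypes = write_meta(adata.obs, obs_names, "col_name",
                        os.path.join(bundle, "col_data.tsv"))
    man = {
        "version": "1.0",
        "shape": [n, p],
        "assays": manifest_assays,
        "row_data_file": "row_data.tsv",
        "col_data_file": "col_data.tsv",
        "row_names_present": True,
        "col_names_present": True,
        "row_data_types": rtypes,
        "col_data_types": ctypes,
    }
    with open(os.path.join(bundle, "manifest.json"), "w") as fh:
        json.dump(man, fh)


def main(argv):
    if len(argv) != 4 or argv[1] not in ("to-h5ad", "from-h5ad"):
        sys.stderr.write(__doc__)
        return 2
    if argv[1] == "to-h5ad":
        to_h5ad(argv[2], argv[3])
    else:
        from_h5ad(argv[2], argv[3])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
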