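{
  "variant_labels": {
    "key": ["S0003:1:1003138:A:G", "S0004:1:1003138:A:G", "S0007:1:1001813:T:C", "S0008:1:1002019:T:A", "S0011:1:1003138:A:C", "S0012:1:1003138:T:A", "S0004:2:2000061:T:G", "S0008:2:2001030:A:G", "S0010:2:2000158:T:A", "S0012:2:2000441:A:AT", "S0009:3:3002122:T:C", "S0011:3:3001170:AT:A", "S0012:3:3001702:T:C", "S0002:1:1000935:C:G", "S0003:1:1000365:G:A", "S0004:3:3001051:T:C", "S0005:1:1000147:A:G", "S0006:2:2000334:G:T", "S0008:2:2000454:T:G", "S0008:1:1001609:T:C", "S0008:1:1000719:C:T", "S0008:2:2000498:T:C", "S0009:1:1003123:A:C", "S0011:3:3002382:T:A", "S0012:2:2000964:A:C"],
    "label": ["somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "somatic", "germline", "germline", "germline", "germline", "germline", "germline", "germline", "germline", "germline", "germline", "germline", "germline"],
    "true_vaf": [0.183708, 0.335875, 0.309976, 0.294212, 0.25751, 0.249974, 0.335875, 0.294212, 0.331978, 0.249974, 0.272653, 0.25751, 0.249974, 0.566601, 0.365134, 0.483125, 0.487097, 0.526916, 0.441236, 0.601467, 0.438868, 0.451527, 0.439877, 0.563703, 0.480144],
    "pop_maf": ["NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", "NA", 0.0214940713631795, 0.0564100754070958, 0.0885096644957289, 0.0908364298387626, 0.130279722414745, 0.100809414448501, 0.021226448453182, 0.181073616549901, 0.0615971782264419, 0.0703351190931484, 0.115377776438409, 0.0316815436798365]
  },
  "gene_loghr": {
    "gene": ["PIK3CA", "TP53", "MAP3K1"],
    "loghr_bcss": [-0.3, 0.5, -0.4],
    "loghr_rfs": [-0.25, 0.45, -0.35],
    "loghr_os": [-0.2, 0.4, -0.3],
    "_row": ["PIK3CA", "TP53", "MAP3K1"]
  },
  "purity": {
    "sample_id": ["S0001", "S0002", "S0003", "S0004", "S0005", "S0006", "S0007", "S0008", "S0009", "S0010", "S0011", "S0012"],
    "purity": [0.649424870367804, 0.717181433171549, 0.367415650899966, 0.671749729116457, 0.639688163704917, 0.515461246755382, 0.619952474392816, 0.588423813804609, 0.545306140711538, 0.663955272023779, 0.515020824289655, 0.499948495072257]
  },
  "mpmb_correction": [1.6]
}
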