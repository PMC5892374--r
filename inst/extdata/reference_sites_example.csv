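ecological_landscape,landform,latitude,longitude
Arctic Peaty Lowland,non-patterned Drained Thaw Lake Basin,71.236855,-156.3785131
Arctic Peaty Lowland,High-center polygon,71.210642,-156.4676783
Arctic Peaty Lowland,Pond,71.191358,-156.3469935
Arctic Peaty Lowland,River,70.181085,-147.2617363
Arctic Peaty Lowland,Riparian corridor,70.165456,-148.4265964
Arctic Sandy Lowland,Lake,70.166375,-154.2431094
Arctic Sandy Lowland,Drained slope,70.160143,-153.6316156
Arctic Sandy Lowland,Sand dune,70.3493,-152.7590333
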