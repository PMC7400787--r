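# Synthetic strand-resolved UV substitution signature (192 channels).
# Constructed stand-in for a published UV signature: C>T at dipyrimidine
# contexts dominates; TCC>TTC pinned at the published probability 0.2887;
# purine-reference (reciprocal-strand) channels down-weighted by 0.25.
# Generated by data-raw/make_uv_signature.R. NOT a published table.
ctx5	ref	alt	ctx3	prob
A	A	C	A	3.2344382591093118e-05
A	A	C	C	3.2344382591093118e-05
A	A	C	G	3.2344382591093118e-05
A	A	C	T	3.2344382591093118e-05
A	A	G	A	0.00038813259109311739
A	A	G	C	6.4688765182186237e-05
A	A	G	G	0.00038813259109311739
A	A	G	T	6.4688765182186237e-05
A	A	T	A	0.0001940662955465587
A	A	T	C	3.2344382591093118e-05
A	A	T	G	0.0001940662955465587
A	A	T	T	3.2344382591093118e-05
A	C	A	A	0.00025875506072874495
A	C	A	C	0.00025875506072874495
A	C	A	G	0.00025875506072874495
A	C	A	T	0.00025875506072874495
A	C	G	A	0.00012937753036437247
A	C	G	C	0.00012937753036437247
A	C	G	G	0.00012937753036437247
A	C	G	T	0.00012937753036437247
A	C	T	A	0.0051751012145748983
A	C	T	C	0.0051751012145748983
A	C	T	G	0.0051751012145748983
A	C	T	T	0.0051751012145748983
A	G	A	A	0.029109944331983804
A	G	A	C	0.0012937753036437246
A	G	A	G	0.019406629554655868
A	G	A	T	0.0012937753036437246
A	G	C	A	3.2344382591093118e-05
A	G	C	C	3.2344382591093118e-05
A	G	C	G	3.2344382591093118e-05
A	G	C	T	3.2344382591093118e-05
A	G	T	A	6.4688765182186237e-05
A	G	T	C	6.4688765182186237e-05
A	G	T	G	6.4688765182186237e-05
A	G	T	T	6.4688765182186237e-05
A	T	A	A	0.00012937753036437247
A	T	A	C	0.00012937753036437247
A	T	A	G	0.00012937753036437247
A	T	A	T	0.00012937753036437247
A	T	C	A	0.00025875506072874495
A	T	C	C	0.00025875506072874495
A	T	C	G	0.00025875506072874495
A	T	C	T	0.00025875506072874495
A	T	G	A	0.00012937753036437247
A	T	G	C	0.00012937753036437247
A	T	G	G	0.00012937753036437247
A	T	G	T	0.00012937753036437247
C	A	C	A	3.2344382591093118e-05
C	A	C	C	3.2344382591093118e-05
C	A	C	G	3.2344382591093118e-05
C	A	C	T	3.2344382591093118e-05
C	A	G	A	0.00038813259109311739
C	A	G	C	6.4688765182186237e-05
C	A	G	G	0.00038813259109311739
C	A	G	T	6.4688765182186237e-05
C	A	T	A	0.0001940662955465587
C	A	T	C	3.2344382591093118e-05
C	A	T	G	0.0001940662955465587
C	A	T	T	3.2344382591093118e-05
C	C	A	A	0.00025875506072874495
C	C	A	C	0.00025875506072874495
C	C	A	G	0.00025875506072874495
C	C	A	T	0.00025875506072874495
C	C	G	A	0.00012937753036437247
C	C	G	C	0.00012937753036437247
C	C	G	G	0.00012937753036437247
C	C	G	T	0.00012937753036437247
C	C	T	A	0.038813259109311736
C	C	T	C	0.084095394736842091
C	C	T	G	0.025875506072874491
C	C	T	T	0.077626518218623472
C	G	A	A	0.009703314777327934
C	G	A	C	0.0012937753036437246
C	G	A	G	0.0064688765182186227
C	G	A	T	0.0012937753036437246
C	G	C	A	3.2344382591093118e-05
C	G	C	C	3.2344382591093118e-05
C	G	C	G	3.2344382591093118e-05
C	G	C	T	3.2344382591093118e-05
C	G	T	A	6.4688765182186237e-05
C	G	T	C	6.4688765182186237e-05
C	G	T	G	6.4688765182186237e-05
C	G	T	T	6.4688765182186237e-05
C	T	A	A	0.00077626518218623479
C	T	A	C	0.00077626518218623479
C	T	A	G	0.00077626518218623479
C	T	A	T	0.00077626518218623479
C	T	C	A	0.0015525303643724696
C	T	C	C	0.0015525303643724696
C	T	C	G	0.0015525303643724696
C	T	C	T	0.0015525303643724696
C	T	G	A	0.00012937753036437247
C	T	G	C	0.00012937753036437247
C	T	G	G	0.00012937753036437247
C	T	G	T	0.00012937753036437247
G	A	C	A	3.2344382591093118e-05
G	A	C	C	3.2344382591093118e-05
G	A	C	G	3.2344382591093118e-05
G	A	C	T	3.2344382591093118e-05
G	A	G	A	0.00038813259109311739
G	A	G	C	6.4688765182186237e-05
G	A	G	G	0.00038813259109311739
G	A	G	T	6.4688765182186237e-05
G	A	T	A	0.0001940662955465587
G	A	T	C	3.2344382591093118e-05
G	A	T	G	0.0001940662955465587
G	A	T	T	3.2344382591093118e-05
G	C	A	A	0.00025875506072874495
G	C	A	C	0.00025875506072874495
G	C	A	G	0.00025875506072874495
G	C	A	T	0.00025875506072874495
G	C	G	A	0.00012937753036437247
G	C	G	C	0.00012937753036437247
G	C	G	G	0.00012937753036437247
G	C	G	T	0.00012937753036437247
G	C	T	A	0.0051751012145748983
G	C	T	C	0.0051751012145748983
G	C	T	G	0.0051751012145748983
G	C	T	T	0.0051751012145748983
G	G	A	A	0.072175000000000003
G	G	A	C	0.0012937753036437246
G	G	A	G	0.021023848684210523
G	G	A	T	0.0012937753036437246
G	G	C	A	3.2344382591093118e-05
G	G	C	C	3.2344382591093118e-05
G	G	C	G	3.2344382591093118e-05
G	G	C	T	3.2344382591093118e-05
G	G	T	A	6.4688765182186237e-05
G	G	T	C	6.4688765182186237e-05
G	G	T	G	6.4688765182186237e-05
G	G	T	T	6.4688765182186237e-05
G	T	A	A	0.00012937753036437247
G	T	A	C	0.00012937753036437247
G	T	A	G	0.00012937753036437247
G	T	A	T	0.00012937753036437247
G	T	C	A	0.00025875506072874495
G	T	C	C	0.00025875506072874495
G	T	C	G	0.00025875506072874495
G	T	C	T	0.00025875506072874495
G	T	G	A	0.00012937753036437247
G	T	G	C	0.00012937753036437247
G	T	G	G	0.00012937753036437247
G	T	G	T	0.00012937753036437247
T	A	C	A	3.2344382591093118e-05
T	A	C	C	3.2344382591093118e-05
T	A	C	G	3.2344382591093118e-05
T	A	C	T	3.2344382591093118e-05
T	A	G	A	0.00038813259109311739
T	A	G	C	6.4688765182186237e-05
T	A	G	G	0.00038813259109311739
T	A	G	T	6.4688765182186237e-05
T	A	T	A	0.0001940662955465587
T	A	T	C	3.2344382591093118e-05
T	A	T	G	0.0001940662955465587
T	A	T	T	3.2344382591093118e-05
T	C	A	A	0.00025875506072874495
T	C	A	C	0.00025875506072874495
T	C	A	G	0.00025875506072874495
T	C	A	T	0.00025875506072874495
T	C	G	A	0.00012937753036437247
T	C	G	C	0.00012937753036437247
T	C	G	G	0.00012937753036437247
T	C	G	T	0.00012937753036437247
T	C	T	A	0.058219888663967607
T	C	T	C	0.28870000000000001
T	C	T	G	0.038813259109311736
T	C	T	T	0.11643977732793521
T	G	A	A	0.014554972165991902
T	G	A	C	0.0012937753036437246
T	G	A	G	0.009703314777327934
T	G	A	T	0.0012937753036437246
T	G	C	A	3.2344382591093118e-05
T	G	C	C	3.2344382591093118e-05
T	G	C	G	3.2344382591093118e-05
T	G	C	T	3.2344382591093118e-05
T	G	T	A	6.4688765182186237e-05
T	G	T	C	6.4688765182186237e-05
T	G	T	G	6.4688765182186237e-05
T	G	T	T	6.4688765182186237e-05
T	T	A	A	0.00077626518218623479
T	T	A	C	0.00077626518218623479
T	T	A	G	0.00077626518218623479
T	T	A	T	0.00077626518218623479
T	T	C	A	0.0015525303643724696
T	T	C	C	0.0015525303643724696
T	T	C	G	0.0015525303643724696
T	T	C	T	0.0015525303643724696
T	T	G	A	0.00012937753036437247
T	T	G	C	0.00012937753036437247
T	T	G	G	0.00012937753036437247
T	T	G	T	0.00012937753036437247
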