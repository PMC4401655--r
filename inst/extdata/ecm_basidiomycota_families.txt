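# Basidiomycete families treated as putatively ectomycorrhizal.
# One family per line; edit or replace via ecm_whitelist(path = ...).
Thelephoraceae
Tricholomataceae
Cortinariaceae
Russulaceae
Cantharellaceae
Amanitaceae
Sebacinaceae
Boletaceae
Inocybaceae
Clavulinaceae
Hydnangiaceae
Sclerodermataceae
Pisolithaceae
Hymenogastraceae
Entolomataceae
Atheliaceae
Bankeraceae
Gomphaceae
Hydnaceae
Paxillaceae
Suillaceae
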