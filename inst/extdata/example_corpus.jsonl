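{"id":"ex1","text":"Lymphoma is found in the lymph system."}
{"id":"ex2","text":"Interacting selectively and non-covalently with a h4 histamine receptor."}
{"id":"ex3","text":"An erythrocyte carries oxygen from the lungs to all parts of the body."}
{"id":"ex4","text":"Hypertension may damage the heart over many years. It is often silent."}
{"id":"ex5","text":"A corticosteroid is given to reduce swelling and pain."}
{"id":"ex6","text":"The test showed a carcinoma in the upper lobe of the lung."}
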