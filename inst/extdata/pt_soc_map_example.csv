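pt,soc
Gastrointestinal haemorrhage,Gastrointestinal disorders
Upper gastrointestinal haemorrhage,Gastrointestinal disorders
Epistaxis,"Respiratory, thoracic and mediastinal disorders"
Haematuria,Renal and urinary disorders
Rectal haemorrhage,Gastrointestinal disorders
Fall,"Injury, poisoning and procedural complications"
Anaemia,Blood and lymphatic system disorders
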