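{"marker_map":{"breast-":["miR-0049","miR-0037","miR-0001","miR-0025"],"breast+":["miR-0010","miR-0036","miR-0018","miR-0060"],"lung-":["miR-0047","miR-0024","miR-0007","miR-0055"],"lung+":["miR-0057","miR-0059","miR-0046","miR-0020"]},"shared_marker_names":["miR-0026","miR-0003","miR-0041"],"net_signature_names":[],"net_sample_ids":[],"planted_outlier_ids":[],"planted_lowdepth_ids":[],"classes":["breast-","breast+","lung-","lung+"]}
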