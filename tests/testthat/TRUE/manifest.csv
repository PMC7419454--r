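"mask","seed","image_size"
"mask_0001.png",1,256
"mask_0002.png",2,256
"mask_0003.png",3,256
"mask_0004.png",4,256
"mask_0005.png",5,256
"mask_0006.png",6,256
"mask_0007.png",7,256
"mask_0008.png",8,256
"mask_0009.png",9,256
"mask_0010.png",10,256
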