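emoji	word
😀	happy
😃	happy
😄	happy
😁	happy
🙂	happy
😊	happy
😍	love
🥰	love
❤️	love
❤	love
💕	love
😂	laughing
🤣	laughing
😅	laughing
😉	smiling
😢	crying
😭	crying
😞	sad
😔	sad
😟	worried
☹️	sad
🙁	sad
💔	heartbroken
😠	angry
😡	angry
🤬	furious
😤	annoyed
😱	terrified
😨	afraid
😰	anxious
😥	sad
😳	surprised
😮	shocked
😲	shocked
🤯	shocked
😴	tired
🙏	thankful
👍	good
👎	bad
🔥	fire
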